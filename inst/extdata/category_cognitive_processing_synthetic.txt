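# Synthetic demonstration word list: cognitive_processing category.
analyze
analyzing
because
believe
believed
cause
causes
consider
considering
decide
decided
effect
know
knowing
known
maybe
meaning
means
ought
perhaps
question
questions
realize
realized
reason
reasons
reflect
reflecting
remember
remembered
should
think
thinking
thought
thoughts
understand
understood
wonder
wondering
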