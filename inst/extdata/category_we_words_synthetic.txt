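# Synthetic demonstration word list: we_words category.
let's
our
ours
ourselves
us
we
we're
we've
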