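# Synthetic demonstration word list: i_words category.
i
i'd
i'll
i'm
i've
me
mine
my
myself
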