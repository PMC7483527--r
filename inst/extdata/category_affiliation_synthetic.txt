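# Synthetic demonstration word list: affiliation category.
allies
ally
belong
bond
club
community
companion
connect
connected
family
friend
friends
group
neighbor
partner
share
sharing
social
team
teammate
together
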