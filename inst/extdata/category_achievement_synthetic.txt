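# Synthetic demonstration word list: achievement category.
accomplish
accomplished
achieve
achieved
achievement
ambition
award
best
better
earn
earned
effort
goal
goals
improve
improved
master
mastered
prize
succeed
success
successful
win
winning
won
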