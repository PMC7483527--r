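# Synthetic demonstration word list: leisure category.
chat
chatting
cook
cooking
dance
dancing
game
games
garden
gardening
hike
hiking
hobby
holiday
movie
movies
music
party
play
playing
read
reading
relax
song
sport
sports
swim
swimming
travel
vacation
weekend
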