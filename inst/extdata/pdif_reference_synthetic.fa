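>CD synthetic consensus-style XerC/XerD pdif reference (11 bp XerC arm | 6 bp central | 11 bp XerD arm)
ATTTCGTATAAGGTGTATTATGTTAATT
>DC synthetic consensus-style XerD/XerC pdif reference (reverse-complement arm order, 2 arm substitutions vs rc(CD))
AATTGACATAATACACCTTATACAAAAT
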