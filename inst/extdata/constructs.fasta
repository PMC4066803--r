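>G_core regular (GGGGA)4 core flanked by di-thymidines
TTGGGGAGGGGAGGGGAGGGGTT
>mutant_core G-less control core
GTTGATTAGATGTGATTAG
>spacer_core synthetic reconstruction: two G-tracts separated by ATTTTA
TTGGGGAATTTTAGGGGATT
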