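id	flank5	flank3	disease_base
var0001	TATATTAATTTTAAAATTTTTATTTTTTAC	TAAAATTAATTTATAATAGTTTTAATTAAATAAATATTTTATTTTATAAA	C
var0002	TTATATAATATAATATATTTATAATATATA	TATTTATTTTAATTAATAAATAATAAAATA	C
var0003	TTAAATTTTTTAAATTAAAAAAAAAAATAC	AAAATAAATATTTTATGGAAATAATTAATATTTATAATTAAAATTTAA	C
var0004	AAAAATTAAATAATTTAATTTTTTTTTAAA	TATTTTTTTAAAAAAAATTAATAAAATAAT	C
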