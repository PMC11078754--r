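# Human-lineage clade ordering, youngest first.
# Used to pick the "younger" clade when a repeat family is listed in
# several clades.
Homo
Homininae
Hominoidea
Catarrhini
Simiiformes
Primates
Euarchontoglires
Eutheria
Theria
Mammalia
Amniota
Tetrapoda
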