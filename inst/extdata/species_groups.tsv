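species	group
human	sensitive
zebrafish	sensitive
frog	sensitive
chicken	sensitive
opossum	sensitive
bushbaby	sensitive
armadillo	sensitive
sheep	sensitive
rabbit	sensitive
golden_hamster	sensitive
marmoset	sensitive
rhesus_macaque	sensitive
mouse	insensitive
rat	insensitive
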