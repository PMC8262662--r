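tf	target	mode
Bmi1	Dkk1	repression
Bmi1	Vegfa	unknown
Bmi1	Kdr	unknown
Ets1	Dkk1	activation
Ets1	Vegfa	activation
Ets1	Kdr	activation
Runx2	Dkk1	unknown
Runx2	Vegfa	activation
Runx2	Kdr	unknown
Ikzf1	Kdr	repression
Trp53	Dkk1	activation
Sall4	Tbx5	activation
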