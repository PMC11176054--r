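locus_id	chrom	start	end	carrier_fREF	carrier_fB	carrier_fC	carrier_fD
Solyc09g018220	chr9	2000000	2100000	1	0	0	0
Solyc06g008720	chr6	1000000	1100000	0	0	1	0
Solyc06g074350	chr6	44000000	44100000	0	1	0	0
Solyc02g089160	chr2	45000000	45100000	0	1	0	0
Solyc11g011180	chr11	4500000	4600000	0	0	0	1
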