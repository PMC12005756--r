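name	subclass	backbone_mass_avg	n_glyc_sites	openSS_truncation_delta	rt_ref
IGHG1*01	IgG1	23790.9	1	-2708.9	700
IGHG1*02	IgG1	23904.9	1	-2708.9	760
IGHG1*03	IgG1	23760.0	1	-2708.9	730
IGHG2*01	IgG2	23564.7	1	-2650.3	845
IGHG2*02	IgG2	23603.4	1	-2650.3	875
IGHG2*06	IgG2	23619.7	1	-2650.3	815
IGHG3*01	IgG3	24095.9	2	-2700.1	980
IGHG3*11	IgG3	24057.9	2	-2700.1	1010
IGHG4*01	IgG4	23517.4	1	-2630.7	1120
IGHG4*02	IgG4	23539.5	1	-2630.7	1150
IGHG4*04	IgG4	23461.9	1	-2630.7	1090
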