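# qmclust results table; energies in kcal/mol
# job_id = <variant>/<point>/<task>/<level>
job_id	electronic_energy	zpe	solvation	dispersion	converged	n_imag
WT/ES/minimize/combined	-12.4	2.1	-3.5	-6.2	TRUE	0
WT/TS_C1/saddle-search/combined	4.4	1.6	-3.8	-6.5	TRUE	1
WT/TS_C2/saddle-search/combined	4.3	1.6	-3.8	-6.5	TRUE	1
R1/ES/minimize/combined	-13.7	2.1	-3.5	-6.2	TRUE	0
R1/TS_C1/saddle-search/combined	1.7	1.6	-3.8	-6.5	TRUE	1
R1/TS_C2/saddle-search/combined	0.5	1.6	-3.8	-6.5	TRUE	1
R2/ES/minimize/combined	-11.6	2.1	-3.5	-6.2	TRUE	0
R2/TS_C1/saddle-search/combined	3.5	1.6	-3.8	-6.5	TRUE	1
R2/TS_C2/saddle-search/combined	3.1	1.6	-3.8	-6.5	TRUE	1
R3/ES/minimize/combined	-13.2	2.1	-3.5	-6.2	TRUE	0
R3/TS_C1/saddle-search/combined	3.2	1.6	-3.8	-6.5	TRUE	1
R3/TS_C2/saddle-search/combined	2.2	1.6	-3.8	-6.5	TRUE	1
S1/ES/minimize/combined	-11.0	2.1	-3.5	-6.2	TRUE	0
S1/TS_C1/saddle-search/combined	4.8	1.6	-3.8	-6.5	TRUE	1
S1/TS_C2/saddle-search/combined	6.2	1.6	-3.8	-6.5	TRUE	1
S2/ES/minimize/combined	-14.5	2.1	-3.5	-6.2	TRUE	0
S2/TS_C1/saddle-search/combined	0.5	1.6	-3.8	-6.5	TRUE	1
S2/TS_C2/saddle-search/combined	4.1	1.6	-3.8	-6.5	TRUE	1
S3/ES/minimize/combined	-12.3	2.1	-3.5	-6.2	TRUE	0
S3/TS_C1/saddle-search/combined	2.0	1.6	-3.8	-6.5	TRUE	1
S3/TS_C2/saddle-search/combined	5.4	1.6	-3.8	-6.5	TRUE	1
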