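# experimental enantioselectivities for the desymmetrization of
# cyclopentene oxide: ee in percent with the favored product, or the
# equivalent barrier difference (kcal/mol) where only that is reported
variant	ee_percent	favored_product	ddg
WT	14	RR	NA
R1	66	RR	NA
R2	73	RR	NA
R3	NA	NA	-1.3
S1	NA	NA	1.0
S2	91	SS	NA
S3	93	SS	NA
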