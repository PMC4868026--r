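name	chrom	start	end	type	note
DYX1C1	15	55790529	55868973	gene	reading disability candidate
KIAA0319	6	24544472	24646383	gene	reading disability candidate
DCDC2	6	24171755	24383950	gene	reading disability candidate
CNTNAP2	7	145813453	148118090	gene	language impairment candidate
FOXP2	7	113726365	114333827	gene	speech/language candidate
CHRNA7	15	32322691	32462384	gene	language/neurodevelopmental candidate
CNTN4	3	2140497	3099645	gene	neurodevelopmental candidate
CTNNA3	10	67672276	69455927	gene	neurodevelopmental candidate
15q13.3	15	30900000	32500000	region	neuropsychiatric CNV hotspot
16p11.2	16	29500000	30200000	region	neuropsychiatric CNV hotspot
22q11.21	22	18700000	21800000	region	neuropsychiatric CNV hotspot
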