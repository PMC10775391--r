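# Published reclassification cell percentages: conventional risk scores vs the
# stacked meta-prediction classifier at its Youden cutoff (0.24), held-out
# incident cohort (events n=3,162; non-events n=30,257).
# call = meta-prediction classification; tier_positive marks old tiers treated
# as positive when collapsing to binary for the categorical NRI.
score	tier	tier_positive	group	call	pct
pce	low_lt5	0	non_event	negative	41.47
pce	low_lt5	0	non_event	positive	2.86
pce	borderline_5_7.5	0	non_event	negative	11.68
pce	borderline_5_7.5	0	non_event	positive	3.16
pce	intermediate_7.5_20	1	non_event	negative	19.57
pce	intermediate_7.5_20	1	non_event	positive	14.68
pce	high_ge20	1	non_event	negative	1.72
pce	high_ge20	1	non_event	positive	4.85
pce	low_lt5	0	event	negative	8.76
pce	low_lt5	0	event	positive	4.97
pce	borderline_5_7.5	0	event	negative	4.71
pce	borderline_5_7.5	0	event	positive	6.33
pce	intermediate_7.5_20	1	event	negative	11.80
pce	intermediate_7.5_20	1	event	positive	40.73
pce	high_ge20	1	event	negative	2.02
pce	high_ge20	1	event	positive	20.68
qrisk3	low_lt10	0	non_event	negative	39.47
qrisk3	low_lt10	0	non_event	positive	2.41
qrisk3	moderate_10_20	1	non_event	negative	26.03
qrisk3	moderate_10_20	1	non_event	positive	9.22
qrisk3	high_ge20	1	non_event	negative	8.94
qrisk3	high_ge20	1	non_event	positive	13.93
qrisk3	low_lt10	0	event	negative	7.81
qrisk3	low_lt10	0	event	positive	4.02
qrisk3	moderate_10_20	1	event	negative	11.86
qrisk3	moderate_10_20	1	event	positive	21.06
qrisk3	high_ge20	1	event	negative	7.62
qrisk3	high_ge20	1	event	positive	47.63
gps	negative_lt0.09	0	non_event	negative	59.28
gps	negative_lt0.09	0	non_event	positive	8.21
gps	positive_ge0.09	1	non_event	negative	15.16
gps	positive_ge0.09	1	non_event	positive	17.35
gps	negative_lt0.09	0	event	negative	16.29
gps	negative_lt0.09	0	event	positive	15.28
gps	positive_ge0.09	1	event	negative	11.01
gps	positive_ge0.09	1	event	positive	57.43
metagrs	negative_lt0.09	0	non_event	negative	57.67
metagrs	negative_lt0.09	0	non_event	positive	7.50
metagrs	positive_ge0.09	1	non_event	negative	16.78
metagrs	positive_ge0.09	1	non_event	positive	18.05
metagrs	negative_lt0.09	0	event	negative	15.50
metagrs	negative_lt0.09	0	event	positive	14.04
metagrs	positive_ge0.09	1	event	negative	11.80
metagrs	positive_ge0.09	1	event	positive	58.67
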