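label	numerator	denominator	printed_pct	digits
study_total_south_africa	113	166	68	0
study_total_australia	53	166	32	0
study_total_lr	35	166	21	0
study_total_hr	131	166	79	0
afr_lr	28	109	26	0
afr_hr	81	109	74	0
eur_lr	7	57	12	0
eur_hr	50	57	88	0
pub_eur_lr	234	296	79	0
pub_eur_hr	62	296	21	0
asi_lr	73	207	35	0
asi_hr	134	207	65	0
afr_very_hr	72	81	89	0
eur_very_hr	49	50	98	0
study_kataegis_positive	68	166	41	0
pub_eur_kataegis_positive	116	296	39.2	1
asi_kataegis_positive	103	207	49.8	1
events_within_10kb	413	831	50	0
events_within_1kb	335	831	40	0
events_spanning_sv	109	831	13	0
clonal_kataegis	128	197	65.0	1
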