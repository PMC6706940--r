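# Published per-cell counts of detectable C-peptide (numerator) out of all
# individuals (denominator) by age-at-onset bin and duration bin.
# Bin indices refer to onset bins [0,15) [15,25) [25,35) [35,Inf) and
# duration bins [0,5) [5,10) [10,15) [15,Inf).
onset_bin	duration_bin	detectable	total
1	1	13	17
2	1	178	186
3	1	161	172
4	1	262	285
1	2	79	128
2	2	110	165
3	2	107	138
4	2	188	253
1	3	60	237
2	3	89	163
3	3	103	197
4	3	129	225
1	4	317	1643
2	4	259	996
3	4	253	705
4	4	174	418
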