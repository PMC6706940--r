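# Published per-cell counts of individuals negative for all three islet
# autoantibodies (numerator) out of all individuals (denominator) by
# duration bin and C-peptide range.
# Bin indices refer to duration bins [0,5) [5,10) [10,15) [15,Inf) and
# C-peptide bins [0,30] (30,200] (200,600] (600,7000] pmol/l.
duration_bin	cpep_bin	abneg	total
1	1	5	92
1	2	15	168
1	3	28	243
1	4	54	155
2	1	49	326
2	2	26	196
2	3	24	87
2	4	47	68
3	1	97	568
3	2	26	122
3	3	25	56
3	4	53	71
4	1	997	3272
4	2	108	300
4	3	68	116
4	4	49	61
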