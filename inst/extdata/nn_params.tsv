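# version: bimodalseed-nn-0.1
# Nearest-neighbour duplex parameters (kcal/mol, 37C).
# stack rows: a = 5' pair, b = 3' pair of the step, pairs coded as
# (strand1 nt)(strand2 nt); table is symmetric under step reversal,
# stack[p1][p2] == stack[swap(p2)][swap(p1)].
# bulge/internal rows: a = total unpaired size, penalty >= 0, nondecreasing.
term	a	b	value
init	.	.	4.09
stack	AU	AU	-0.93
stack	AU	UA	-1.10
stack	AU	CG	-2.24
stack	AU	GC	-2.08
stack	AU	GU	-0.55
stack	AU	UG	-1.36
stack	UA	AU	-1.33
stack	UA	UA	-0.93
stack	UA	CG	-2.35
stack	UA	GC	-2.11
stack	UA	GU	-1.27
stack	UA	UG	-1.00
stack	CG	AU	-2.11
stack	CG	UA	-2.08
stack	CG	CG	-3.26
stack	CG	GC	-2.36
stack	CG	GU	-1.41
stack	CG	UG	-2.11
stack	GC	AU	-2.35
stack	GC	UA	-2.24
stack	GC	CG	-3.42
stack	GC	GC	-3.26
stack	GC	GU	-1.53
stack	GC	UG	-2.51
stack	GU	AU	-1.00
stack	GU	UA	-1.36
stack	GU	CG	-2.51
stack	GU	GC	-2.11
stack	GU	GU	-0.50
stack	GU	UG	0.50
stack	UG	AU	-1.27
stack	UG	UA	-0.55
stack	UG	CG	-1.53
stack	UG	GC	-1.41
stack	UG	GU	-0.60
stack	UG	UG	-0.50
bulge	1	.	2.90
bulge	2	.	3.10
bulge	3	.	3.50
bulge	4	.	3.90
bulge	5	.	4.20
bulge	6	.	4.40
bulge	7	.	4.60
bulge	8	.	4.80
bulge	9	.	4.90
bulge	10	.	5.00
internal	2	.	1.50
internal	3	.	1.70
internal	4	.	1.70
internal	5	.	2.00
internal	6	.	2.20
internal	7	.	2.30
internal	8	.	2.40
internal	9	.	2.50
internal	10	.	2.60
internal	11	.	2.70
internal	12	.	2.80
internal	13	.	2.90
internal	14	.	3.00
internal	15	.	3.10
internal	16	.	3.20
internal	17	.	3.30
internal	18	.	3.40
internal	19	.	3.50
internal	20	.	3.60
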