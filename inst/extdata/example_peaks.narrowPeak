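chr1	500	900	p1	100	.	5.0	4.0	3.0	200
chr1	0	300	p2	90	.	5.0	4.0	3.0	50
chr1	1000	1400	p3	80	.	5.0	4.0	3.0	200
chr1	1000	1400	p4	70	.	5.0	4.0	3.0	200
chr1	2000	2400	p5	60	.	5.0	4.0	3.0	-1
chr2	4800	5000	p6	50	.	5.0	4.0	3.0	150
chr1	3000	3200	p7	40	.	5.0	4.0	3.0	100
chr1	4000	4404	p8	30	.	5.0	4.0	3.0	4
chr2	100	500	p9	20	.	5.0	4.0	3.0	300
chr1	6000	6400	p10	10	.	5.0	4.0	3.0	100
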