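# Partially printed (ellipsis) deletion junctions: only the first and
# last bases of the deleted segment are catalogued.
allele_id	left_flank	del_prefix	del_suffix	right_flank	declared_size	mh_marked
C-162-gl1	AGTGGTCTT	cttcgc	ctcctt	AGAGTT	51	3
C(450)-135-hy1	AAAACTCA	caa	cagttca	AGAG	36	3
C(450)-154-hy1	AACTAA	accgta	ggtatg	GTTCA	32335	0
C30-273-var1	GGTTTGT	tcctt	gtctggt	GGTGG	23	2
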