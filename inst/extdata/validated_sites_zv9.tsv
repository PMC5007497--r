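# Ten experimentally supported zebrafish p53 binding sites (Zv9/danRer7
# assembly, 1-based inclusive coordinates).
gene	chrom	start	end	region	in_repeat
hspa8	10	30761068	30761101	exon	No
stat3	3	16723031	16723052	intron	No
axin1	3	43009715	43009734	intron	Yes
vcp	5	43134399	43134429	intron	Yes
runx1	1	1067563	1067595	intron	No
dnajc9	12	10255976	10256007	upstream	No
traf4a	15	14555737	14555756	five_prime_UTR	No
necab2	18	21197526	21197546	upstream	No
ttyh2l	3	52217686	52217707	upstream	No
col4a5	7	52559622	52559647	upstream	No
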