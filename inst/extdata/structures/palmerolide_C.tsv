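#bgc_id	palmerolide_C
#E	11
#starter	3-methylcrotonic_acid
#n_glycine	1
#tail_extension	0
#tail_methyls	0
#terminal_olefin	FALSE
#ring_to	19
#hydrolyzed	FALSE
#alpha_hydroxyls	8
position	source	hydroxyl	stereo	ketone	olefin	geometry	methyl	methyl_carbon	branch	branch_carbon	branch_internal_olefin	decoration
1	polyketide	FALSE	NA	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	NA
2	polyketide	FALSE	NA	FALSE	TRUE	trans	FALSE	NA	FALSE	NA	FALSE	NA
3	polyketide	FALSE	NA	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	NA
4	polyketide	FALSE	NA	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	NA
5	polyketide	FALSE	NA	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	NA
6	polyketide	FALSE	NA	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	NA
7	polyketide	TRUE	D	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	free
8	polyketide	TRUE	NA	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	free
9	polyketide	FALSE	NA	FALSE	TRUE	trans	FALSE	NA	FALSE	NA	FALSE	NA
10	polyketide	FALSE	NA	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	NA
11	polyketide	TRUE	D	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	carbamate
12	polyketide	FALSE	NA	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	NA
13	polyketide	FALSE	NA	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	NA
14	polyketide	FALSE	NA	FALSE	TRUE	trans	FALSE	NA	FALSE	NA	FALSE	NA
15	polyketide	FALSE	NA	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	NA
16	polyketide	FALSE	NA	FALSE	TRUE	NA	FALSE	NA	FALSE	NA	FALSE	NA
17	polyketide	FALSE	NA	FALSE	FALSE	NA	FALSE	NA	TRUE	25	TRUE	NA
18	polyketide	FALSE	NA	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	NA
19	polyketide	TRUE	L	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	lactone
20	polyketide	FALSE	NA	FALSE	FALSE	NA	TRUE	26	FALSE	NA	FALSE	NA
21	polyketide	FALSE	NA	FALSE	TRUE	trans	FALSE	NA	FALSE	NA	FALSE	NA
22	polyketide	FALSE	NA	FALSE	FALSE	NA	TRUE	27	FALSE	NA	FALSE	NA
23	glycine	FALSE	NA	FALSE	TRUE	trans	FALSE	NA	FALSE	NA	FALSE	NA
24	glycine	FALSE	NA	FALSE	FALSE	NA	FALSE	NA	FALSE	NA	FALSE	NA
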