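# Contact typing table: symmetric map from unordered atom-group pairs (see
# atom_groups.tsv) to 14 contact types (0..13). Anchored assignments:
#   type 0  hydrogen-bond contacts (donor-acceptor)
#   type 2  C_c with oxygen/nitrogen
#   type 3  hydrophobic contacts between C_c
#   type 4  C_on with oxygen/nitrogen
#   type 5  C_on with C_c
#   type 9  pi-involving contacts
#   type 13 acceptor-acceptor contacts
# Remaining types fill out the 14 (reconstruction; the exact published
# partition is not reproduced here):
#   type 1  C_on with C_on; type 6 neutral donor-donor; type 7 sulfur
#   contacts; type 8 water-polar; type 10 salt bridge (Nc-Oc);
#   type 11 water-apolar/sulfur/water; type 12 charged donor-donor
group_a	group_b	type
0	0	3
0	1	5
0	2	2
0	3	2
0	4	2
0	5	2
0	6	2
0	7	7
0	8	9
0	9	11
1	1	1
1	2	4
1	3	4
1	4	4
1	5	4
1	6	4
1	7	7
1	8	9
1	9	11
2	2	6
2	3	6
2	4	0
2	5	0
2	6	0
2	7	7
2	8	9
2	9	8
3	3	12
3	4	0
3	5	10
3	6	0
3	7	7
3	8	9
3	9	8
4	4	13
4	5	13
4	6	0
4	7	7
4	8	9
4	9	8
5	5	13
5	6	0
5	7	7
5	8	9
5	9	8
6	6	0
6	7	7
6	8	9
6	9	8
7	7	7
7	8	9
7	9	11
8	8	9
8	9	9
9	9	11
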