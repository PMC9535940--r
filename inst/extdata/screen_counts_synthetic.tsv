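# Synthetic worked-example count table for the three-filter pipeline.
# Seven benchmark mutations are configured to pass all three filters;
# three decoys each violate exactly one filter: A289V fails the >1%
# frequency filter only, L861Q fails the >8-fold enrichment filter only,
# M600T passes both numeric filters but is absent from the catalogue
# fixture. Nucleotide keys and per-experiment count splits are synthetic;
# coverage is a uniform 100000. Conditions: actA/actB = activation
# selections (experiments A and B), lof = loss-of-function reference.
nt_pos	ref	alt	protein_change	actA	actB	lof	cov_actA	cov_actB	cov_lof
866	C	T	A289V	900	850	1	100000	100000	100000
1325	G	T	S442I	3000	120	10	100000	100000	100000
1799	T	C	M600T	2600	2400	15	100000	100000	100000
1973	T	A	L658Q	1800	1500	5	100000	100000	100000
2303	G	T	S768I	2500	2100	20	100000	100000	100000
2369	C	T	T790M	4200	300	400	100000	100000	100000
2573	T	G	L858R	5200	4800	30	100000	100000	100000
2582	T	A	L861Q	2000	1900	300	100000	100000	100000
2781	G	A	L927L	900	1300	40	100000	100000	100000
3385	C	T	H1129Y	1100	800	60	100000	100000	100000
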