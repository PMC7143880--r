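# Expert conservation map for TP-A0598 vs NBRC 3934: the five gene clusters
# present in both genomes (the published boldface annotation).
cluster_id_A	cluster_id_B	score
t1pks-1	t1pks-1	1
t1pks-2	t1pks-2	1
t2pks-1	t2pks-1	1
t3pks-1	t3pks-1	1
nrps-1	nrps-1	1
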