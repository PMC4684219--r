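# Shared study set: the 20-complex planted-signal benchmark (seed-fixed).
# Built once; used by the model-recovery and acceptance tests.
BENCH <- make_benchmark_set(n_complexes = 20, n_mutations = 15, seed = 1)
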