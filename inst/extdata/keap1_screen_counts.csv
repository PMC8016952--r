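key,value
n_overlap,96
n_pi_only,106
n_ti_only,127
n_random,291
n_assayed,620
n_available,2684
n_library,12593
top_n,1000
n_substructure_tested,17
n_substructure_hits,5
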