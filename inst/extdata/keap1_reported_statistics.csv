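statistic,value
primary_hits,16
specific_hits,15
hit_rate_pi_pct,5.9
hit_rate_ti_pct,2.7
hit_rate_random_pct,1.0
possible_hits,37
possible_hit_rate_pct,1.4
possible_hit_rate_specific_pct,1.3
library_hit_rate_available_pct,0.56
library_hit_rate_total_pct,0.12
substructure_hit_rate_pct,29.4
availability_pct,21.3
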