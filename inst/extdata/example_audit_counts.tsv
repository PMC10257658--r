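count	value
n_guides	163
n_founders	50
n_predicted_sites	555032
n_sites_with_variants	23
n_hits	26
n_validated	10
founders_with_hits	15
founders_with_validated	8
guides_with_validated	8
founders_confirmed	49
n_hits_nongenic	25
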