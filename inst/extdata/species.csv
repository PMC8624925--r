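species,n_target_copies,ploidy,monoploid_weight_pg
Crocus sativus,2/3,3,7.87
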