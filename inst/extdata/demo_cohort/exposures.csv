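"patient_id","day","nsaid","nephrotoxic_abx","chemo","vascular_imaging","surgery","contrast_ct","icu_transfer"
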