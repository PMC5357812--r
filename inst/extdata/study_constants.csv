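name,value
total_raw_fixes,42467
total_screened_fixes,37054
n_individuals,10
transmitter_mass_g,74
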