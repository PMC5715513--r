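# Exact-count fixture: registry flow and arm sizes realized deterministically.
registry_rows: 27932
duplicate_rows: 2083
invalid_date_rows: 22
distinct_definite: 912
total_definite: 1991
distinct_suspected: 228
total_suspected: 663
n_any_imaging: 438
n_within_30: 239
n_within_1: 212
seed: 1
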