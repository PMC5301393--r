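{"min_identity":0.3,"min_coverage":0.5,"min_score":40,"dit_bands":{"classical_max":270,"classical_p2_max":350,"evolved_min":450},"tal_long_min":850,"tal_short_max":450,"bppu_extended_min":400}
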