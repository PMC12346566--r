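# Default balancing plan: per-class targets drawn on [720, 760] at run time.
classical_fraction: 0.6
extreme_minority_factor: 25
extreme_minority_classes: [LRTI, asthma, bronchiolitis]
threshold: 0.85
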