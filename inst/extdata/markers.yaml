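vocabulary:
- MMP-9
- ELANE
- TGF-b
- CRP
- PCT
- IL-6
- IFN-a
- CXCL10
- TLR3
- IL-1b
- TNF-a
- SP-D
- POSTN
- IL-5
- YKL-40
- fibrinogen
- CC16
- IL-8
- G-CSF
- MUC5AC
baseline: 0.1
diseases:
  asthma:
    POSTN: 0.8
    IL-5: 0.8
    YKL-40: 0.8
  bronchiectasis:
    MMP-9: 0.8
    ELANE: 0.8
    TGF-b: 0.8
  bronchiolitis:
    IL-8: 0.8
    G-CSF: 0.8
    MUC5AC: 0.8
  COPD:
    IL-6: 0.8
    fibrinogen: 0.8
    CC16: 0.8
  healthy: {}
  LRTI:
    IL-1b: 0.8
    TNF-a: 0.8
    SP-D: 0.8
  pneumonia:
    CRP: 0.8
    PCT: 0.8
    IL-6: 0.8
  URTI:
    IFN-a: 0.8
    CXCL10: 0.8
    TLR3: 0.8
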