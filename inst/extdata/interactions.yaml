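# High-risk drug-drug interaction screen: 25 anticoagulant-centred pairs.
# When a patient's co-medication pairs with the formulary's first-line drug,
# the listed alternate is dispensed instead (falling back to supportive care
# if the alternate itself pairs).
anticoagulants: [Warfarin, Apixaban, Rivaroxaban, Dabigatran, Enoxaparin]
pairs:
  # macrolide / tetracycline potentiation of anticoagulants
  - {a: Warfarin,    b: Azithromycin}
  - {a: Apixaban,    b: Azithromycin}
  - {a: Rivaroxaban, b: Azithromycin}
  - {a: Dabigatran,  b: Azithromycin}
  - {a: Enoxaparin,  b: Azithromycin}
  - {a: Warfarin,    b: Doxycycline}
  - {a: Apixaban,    b: Doxycycline}
  - {a: Rivaroxaban, b: Doxycycline}
  - {a: Dabigatran,  b: Doxycycline}
  - {a: Enoxaparin,  b: Doxycycline}
  # NSAID bleeding risk
  - {a: Warfarin,    b: Ibuprofen}
  - {a: Apixaban,    b: Ibuprofen}
  - {a: Rivaroxaban, b: Ibuprofen}
  - {a: Dabigatran,  b: Ibuprofen}
  - {a: Enoxaparin,  b: Ibuprofen}
  # other macrolides kept for screen completeness
  - {a: Warfarin,    b: Clarithromycin}
  - {a: Apixaban,    b: Clarithromycin}
  - {a: Rivaroxaban, b: Clarithromycin}
  - {a: Dabigatran,  b: Clarithromycin}
  - {a: Enoxaparin,  b: Clarithromycin}
  - {a: Warfarin,    b: Erythromycin}
  - {a: Apixaban,    b: Erythromycin}
  - {a: Rivaroxaban, b: Erythromycin}
  - {a: Dabigatran,  b: Erythromycin}
  - {a: Enoxaparin,  b: Erythromycin}
alternates:
  Azithromycin: {drug: Amoxicillin, dosage: 500 mg, frequency: Every 8 h}
  Doxycycline:  {drug: Amoxicillin, dosage: 500 mg, frequency: Every 8 h}
  Ibuprofen:    {drug: Supportive Care Only, dosage: N/A, frequency: N/A}
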