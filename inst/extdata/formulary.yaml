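# Formulary: (diagnosis x age band [x smoking]) -> drug / dosage / frequency.
# The codomain is exactly the recommender's three output vocabularies
# (10 drug categories, 14 dosage classes, 10 frequency classes).
# Editable; assign_prescription() validates vocabulary closure at load time.
age_bands:
  child: [1, 11]
  adult: [12, 64]
  senior: [65, 95]
renal_cleared:            # drugs whose mg dosing follows the eGFR adjustment
  - Azithromycin
  - Amoxicillin
rules:
  healthy:
    child:  {drug: Supportive Care Only, dosage: N/A, frequency: N/A}
    adult:  {drug: Supportive Care Only, dosage: N/A, frequency: N/A}
    senior: {drug: Supportive Care Only, dosage: N/A, frequency: N/A}
  asthma:
    child:  {drug: Budesonide, dosage: 0.5 mg, frequency: Twice daily}
    adult:  {drug: Fluticasone, dosage: 88 mcg, frequency: Twice daily}
    adult_smoker:  {drug: Albuterol, dosage: 2 puffs, frequency: Every 4 to 6 h (PRN)}
    senior: {drug: Fluticasone, dosage: 88 mcg, frequency: Twice daily}
    senior_smoker: {drug: Albuterol, dosage: 2 puffs, frequency: Every 4 to 6 h (PRN)}
  COPD:
    child:  {drug: Albuterol, dosage: 0.63-1.25 mg, frequency: Every 4 to 6 h (PRN)}
    adult:  {drug: Tiotropium, dosage: 1 puff (18 mcg), frequency: Once daily}
    senior: {drug: Tiotropium, dosage: 1 puff (18 mcg), frequency: Once daily}
  pneumonia:
    child:  {drug: Amoxicillin, dosage: 90 mg/kg/day, frequency: Divided in 2 doses}
    adult:  {drug: Azithromycin, dosage: 500 mg, frequency: Once daily for 3-5 days}
    senior: {drug: Azithromycin, dosage: 500 mg, frequency: Once daily for 3-5 days}
  URTI:
    child:  {drug: Ibuprofen, dosage: 10 mg/kg, frequency: Every 6 to 8 h (PRN)}
    adult:  {drug: Ibuprofen, dosage: 400 mg, frequency: Every 6 to 8 h (PRN)}
    adult_smoker: {drug: Ibuprofen, dosage: 400-600 mg, frequency: 3 to 4 times}
    senior: {drug: Ibuprofen, dosage: 400 mg, frequency: Every 6 to 8 h (PRN)}
  bronchiolitis:
    child:  {drug: Hypertonic Saline, dosage: 4 mL of 7% saline, frequency: Every 8 h}
    adult:  {drug: Hypertonic Saline, dosage: 4 mL of 7% saline, frequency: Every 8 h}
    senior: {drug: Hypertonic Saline, dosage: 4 mL of 7% saline, frequency: Every 8 h}
  bronchiectasis:
    child:  {drug: Azithromycin, dosage: 10 mg/kg, frequency: Once daily}
    adult:  {drug: Azithromycin, dosage: 250 mg, frequency: Once daily}
    senior: {drug: Azithromycin, dosage: 250 mg, frequency: Once daily}
  LRTI:
    child:  {drug: Amoxicillin, dosage: 90 mg/kg/day, frequency: Divided in 2 doses}
    adult:  {drug: Doxycycline, dosage: 100 mg, frequency: Twice daily for 7-14 days}
    senior: {drug: Doxycycline, dosage: 100 mg, frequency: Twice daily for 7-14 days}
drug_classes:
  beta_blocker: [Propranolol, Atenolol, Metoprolol, Carvedilol]
contraindications:
  # class-level: never emit a beta-blocker for asthma
  - {diagnosis: asthma, avoid_class: beta_blocker}
  # NSAID avoided under renal impairment; supportive care instead
  - drug: Ibuprofen
    when: renal_impaired
    alternate: {drug: Supportive Care Only, dosage: N/A, frequency: N/A}
  # tetracyclines contraindicated under age 12
  - drug: Doxycycline
    when: age_lt_12
    alternate: {drug: Amoxicillin, dosage: 90 mg/kg/day, frequency: Divided in 2 doses}
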