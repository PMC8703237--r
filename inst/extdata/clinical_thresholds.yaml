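# Declarative definitions of the 20 dichotomous clinical variables.
# Conventions: comparator boundaries are inclusive for >= / <=, strict for
# > / <; 'threshold' may be a single number or a sex-specific map (M/F);
# bands are lower-inclusive, upper-exclusive; type 'all' is the AND of its
# terms; type 'flag' passes a logical column through; type 'equals' tests a
# categorical column against 'value'.
version: 1
phenotypes:
  - name: low_egfr
    type: threshold
    source: egfr
    comparator: "<="
    threshold: 60
    units: mL/min/1.73m2
  - name: high_triglycerides
    type: threshold
    source: trig
    comparator: ">="
    threshold: 2.3
    units: mmol/L
  - name: high_ldl_chol
    type: threshold
    source: ldl
    comparator: ">="
    threshold: 4.1
    units: mmol/L
  - name: high_totchol
    type: threshold
    source: totchol
    comparator: ">="
    threshold: 6.2
    units: mmol/L
  - name: low_hdl_chol
    type: threshold
    source: hdl
    comparator: "<="
    threshold: 1.3
    units: mmol/L
  - name: diabetes
    type: flag
    source: diabetes
  - name: metabolic_syndrome
    type: flag
    source: metabolic_syndrome
  - name: sex
    type: equals
    source: sex
    value: M
  - name: lipid_medication
    type: flag
    source: lipid_medication
  - name: low_age
    type: threshold
    source: age
    comparator: "<"
    threshold: 45
    units: years
  - name: high_hscrp
    type: threshold
    source: hscrp
    comparator: ">"
    threshold: 3
    units: mg/L
  - name: blood_pressure_lowering_med
    type: flag
    source: blood_pressure_lowering_med
  - name: high_age
    type: threshold
    source: age
    comparator: ">="
    threshold: 65
    units: years
  - name: obesity
    type: all
    terms:
      - source: bmi
        comparator: ">="
        threshold: 30
        units: kg/m2
      - source: waist
        comparator: ">="
        threshold:
          M: 102
          F: 93
        units: cm
  - name: low_hgb
    type: threshold
    source: hgb
    comparator: "<="
    threshold:
      M: 6.67
      F: 7.62
    units: mmol/L
  - name: low_wbc
    type: threshold
    source: wbc
    comparator: "<="
    threshold: 4.5
    units: 1e9/L
  - name: current_smoking
    type: flag
    source: current_smoking
  - name: alcohol_consumption
    type: flag
    source: alcohol_consumption
  - name: middle_age
    type: band
    source: age
    lower: 45
    upper: 65
    units: years
  - name: high_pressure
    type: all
    terms:
      - source: systolic
        comparator: ">="
        threshold: 140
        units: mmHg
      - source: diastolic
        comparator: ">="
        threshold: 90
        units: mmHg
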