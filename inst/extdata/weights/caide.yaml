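# CAIDE weight table. Physical activity is the index's own binary
# (active = at least 30 min at least twice a week); age bands are the
# midlife CAIDE bands resolved on baseline age.
index: CAIDE
source: Table 1
version: 1
entries:
  - {factor: sex, level: female, points: 0, demographic: true, source_quote: "Women ... 0"}
  - {factor: sex, level: male,   points: 1, demographic: true, source_quote: "Men ... 1"}
  - {factor: age, level: "<47",   age_min: 0,  age_max: 46,  points: 0, demographic: true, source_quote: "<47 ... 0"}
  - {factor: age, level: "47-53", age_min: 47, age_max: 53,  points: 3, demographic: true, source_quote: "47-53 ... 3"}
  - {factor: age, level: ">53",   age_min: 54, age_max: 200, points: 5, demographic: true, source_quote: ">53 ... 5"}
  - {factor: education, level: low,    points: 4, demographic: true, source_quote: "<8 years / Low ... 4"}
  - {factor: education, level: medium, points: 3, demographic: true, source_quote: "8-11 years / Medium ... 3"}
  - {factor: education, level: high,   points: 0, demographic: true, source_quote: ">11 years / High ... 0"}
  - {factor: apoe4, level: non_carrier, points: 0, source_quote: "Non-carrier ... 0"}
  - {factor: apoe4, level: carrier,     points: 2, source_quote: "Carrier ... 2"}
  - {factor: bmi, level: underweight, points: 0, source_quote: "Underweight (<18.5) ... 0"}
  - {factor: bmi, level: normal,      points: 0, source_quote: "Normal (18.5-24.99) ... 0"}
  - {factor: bmi, level: overweight,  points: 0, source_quote: "Overweight (25-29.99) ... 0"}
  - {factor: bmi, level: obese,       points: 2, source_quote: "Obese (>=30) ... 2"}
  - {factor: hypercholesterolemia, level: no,  points: 0, source_quote: "No ... 0"}
  - {factor: hypercholesterolemia, level: yes, points: 1, source_quote: "Yes ... 1"}
  - {factor: hypertension, level: no,  points: 0, source_quote: "No (Systolic <140 mm Hg) ... 0"}
  - {factor: hypertension, level: yes, points: 2, source_quote: "Yes (Systolic >=140 mm Hg) ... 2"}
  - {factor: physical_activity_caide, level: active,   points: 0, source_quote: "Medium/High ... 0"}
  - {factor: physical_activity_caide, level: inactive, points: 1, source_quote: "Low ... 1"}
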