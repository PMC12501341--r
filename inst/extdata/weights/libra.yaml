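# LIBRA weight table. The index is lifestyle-only by construction; the age
# and education entries are borrowed demographic weights (parenthesized in
# the source table) so the index can be compared with and without
# demographics. Chronic kidney disease is omitted (no data).
index: LIBRA
source: Table 1
version: 1
entries:
  - {factor: age, level: "<65",   sex: male,   age_min: 0,  age_max: 64,  points: 0,    demographic: true, borrowed: true, source_quote: "(0)"}
  - {factor: age, level: "65-69", sex: male,   age_min: 65, age_max: 69,  points: 0.4,  demographic: true, borrowed: true, source_quote: "(0.4)"}
  - {factor: age, level: "70-74", sex: male,   age_min: 70, age_max: 74,  points: 5.2,  demographic: true, borrowed: true, source_quote: "(5.2)"}
  - {factor: age, level: "75-79", sex: male,   age_min: 75, age_max: 79,  points: 6.8,  demographic: true, borrowed: true, source_quote: "(6.8)"}
  - {factor: age, level: "80-84", sex: male,   age_min: 80, age_max: 84,  points: 11.2, demographic: true, borrowed: true, source_quote: "(11.2)"}
  - {factor: age, level: "85-89", sex: male,   age_min: 85, age_max: 89,  points: 14.1, demographic: true, borrowed: true, source_quote: "(14.1)"}
  - {factor: age, level: ">90",   sex: male,   age_min: 90, age_max: 200, points: 16.4, demographic: true, borrowed: true, source_quote: "(16.4)"}
  - {factor: age, level: "<65",   sex: female, age_min: 0,  age_max: 64,  points: 0,    demographic: true, borrowed: true, source_quote: "(0)"}
  - {factor: age, level: "65-69", sex: female, age_min: 65, age_max: 69,  points: 2.1,  demographic: true, borrowed: true, source_quote: "(2.1)"}
  - {factor: age, level: "70-74", sex: female, age_min: 70, age_max: 74,  points: 6.2,  demographic: true, borrowed: true, source_quote: "(6.2)"}
  - {factor: age, level: "75-79", sex: female, age_min: 75, age_max: 79,  points: 9.2,  demographic: true, borrowed: true, source_quote: "(9.2)"}
  - {factor: age, level: "80-84", sex: female, age_min: 80, age_max: 84,  points: 12.4, demographic: true, borrowed: true, source_quote: "(12.4)"}
  - {factor: age, level: "85-89", sex: female, age_min: 85, age_max: 89,  points: 15.3, demographic: true, borrowed: true, source_quote: "(15.3)"}
  - {factor: age, level: ">90",   sex: female, age_min: 90, age_max: 200, points: 17.6, demographic: true, borrowed: true, source_quote: "(17.6)"}
  - {factor: education, level: low,    points: 2.7, demographic: true, borrowed: true, source_quote: "(2.7)"}
  - {factor: education, level: medium, points: 1.4, demographic: true, borrowed: true, source_quote: "(1.4)"}
  - {factor: education, level: high,   points: 0,   demographic: true, borrowed: true, source_quote: "(0)"}
  - {factor: alcohol, level: none,         points: 0,  source_quote: "None ... 0"}
  - {factor: alcohol, level: low_moderate, points: -1, source_quote: "Light-Moderate (1-14 units/wk) ... -1"}
  - {factor: alcohol, level: high,         points: 0,  source_quote: "Excessive (>=14 units/wk) ... 0"}
  - {factor: bmi, level: underweight, points: 0,   source_quote: "Underweight (<18.5) ... - (dash; transcribed 0)"}
  - {factor: bmi, level: normal,      points: 0,   source_quote: "Normal (18.5-24.99) ... 0"}
  - {factor: bmi, level: overweight,  points: 0,   source_quote: "Overweight (25-29.99) ... 0"}
  - {factor: bmi, level: obese,       points: 1.6, source_quote: "Obese (>=30) ... 1.6"}
  - {factor: cognitive_activity, level: low,    points: 0,    source_quote: "Low ... 0"}
  - {factor: cognitive_activity, level: medium, points: 0,    source_quote: "Medium ... 0"}
  - {factor: cognitive_activity, level: high,   points: -3.2, source_quote: "High ... -3.2 (printed run-on; see vignette)"}
  - {factor: heart_disease, level: no,  points: 0, source_quote: "No ... - (dash; transcribed 0)"}
  - {factor: heart_disease, level: yes, points: 1, source_quote: "Yes ... 1"}
  - {factor: depression, level: no,  points: 0,   source_quote: "No ... 0"}
  - {factor: depression, level: yes, points: 2.1, source_quote: "Yes ... 2.1"}
  - {factor: diabetes, level: no,  points: 0,   source_quote: "No ... 0"}
  - {factor: diabetes, level: yes, points: 1.3, source_quote: "Yes ... 1.3"}
  - {factor: mediterranean_diet, level: yes, points: -1.7, source_quote: "Yes ... -1.7"}
  - {factor: mediterranean_diet, level: no,  points: 0,    source_quote: "No ... 0"}
  - {factor: hypercholesterolemia, level: no,  points: 0,   source_quote: "No ... 0"}
  - {factor: hypercholesterolemia, level: yes, points: 1.4, source_quote: "Yes ... 1.4"}
  - {factor: hypertension, level: no,  points: 0,   source_quote: "No (Systolic <140 mm Hg) ... 0"}
  - {factor: hypertension, level: yes, points: 1.6, source_quote: "Yes (Systolic >=140 mm Hg) ... 1.6"}
  - {factor: physical_activity, level: low,    points: 1.1, source_quote: "Low ... 1.1"}
  - {factor: physical_activity, level: medium, points: 0,   source_quote: "Medium ... 0"}
  - {factor: physical_activity, level: high,   points: 0,   source_quote: "High ... 0"}
  - {factor: smoking, level: never,   points: 0,   source_quote: "No ... 0"}
  - {factor: smoking, level: former,  points: 0,   source_quote: "Former Smoker ... - (grouped with non-smokers)"}
  - {factor: smoking, level: current, points: 1.5, source_quote: "Yes ... 1.5"}
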