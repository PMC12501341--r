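# LIBRA2 weight table. Extends LIBRA with sleep problems, social activity
# and hearing impairment; weights are the rescaled (all non-negative)
# LIBRA2 point system. Demographic entries are borrowed (parenthesized in
# the source table). Chronic kidney disease is omitted (no data).
index: LIBRA2
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
  - {factor: alcohol, level: none,         points: 0,   source_quote: "None ... 0"}
  - {factor: alcohol, level: low_moderate, points: 0,   source_quote: "Light-Moderate (1-14 units/wk) ... 0"}
  - {factor: alcohol, level: high,         points: 3.1, source_quote: "Excessive (>=14 units/wk) ... 3.1"}
  - {factor: bmi, level: underweight, points: 0, source_quote: "Underweight (<18.5) ... - (dash; transcribed 0)"}
  - {factor: bmi, level: normal,      points: 0, source_quote: "Normal (18.5-24.99) ... 0"}
  - {factor: bmi, level: overweight,  points: 0, source_quote: "Overweight (25-29.99) ... 0"}
  - {factor: bmi, level: obese,       points: 7, source_quote: "Obese (>=30) ... 7"}
  - {factor: cognitive_activity, level: low,    points: 9.4, source_quote: "Low ... 9.4"}
  - {factor: cognitive_activity, level: medium, points: 0,   source_quote: "Medium ... 0"}
  - {factor: cognitive_activity, level: high,   points: 0,   source_quote: "High ... 0"}
  - {factor: heart_disease, level: no,  points: 0,   source_quote: "No ... - (dash; transcribed 0)"}
  - {factor: heart_disease, level: yes, points: 8.3, source_quote: "Yes ... 8.3"}
  - {factor: depression, level: no,  points: 0,  source_quote: "No ... 0"}
  - {factor: depression, level: yes, points: 13, source_quote: "Yes ... 13"}
  - {factor: diabetes, level: no,  points: 0,   source_quote: "No ... 0"}
  - {factor: diabetes, level: yes, points: 6.8, source_quote: "Yes ... 6.8"}
  - {factor: mediterranean_diet, level: yes, points: 0,   source_quote: "Yes ... 0"}
  - {factor: mediterranean_diet, level: no,  points: 3.8, source_quote: "No ... 3.8"}
  - {factor: hearing, level: no,  points: 0,   source_quote: "No ... 0"}
  - {factor: hearing, level: yes, points: 7.6, source_quote: "Yes ... 7.6"}
  - {factor: hypercholesterolemia, level: no,  points: 0,   source_quote: "No ... 0"}
  - {factor: hypercholesterolemia, level: yes, points: 8.2, source_quote: "Yes ... 8.2"}
  - {factor: hypertension, level: no,  points: 0,   source_quote: "No (Systolic <140 mm Hg) ... 0"}
  - {factor: hypertension, level: yes, points: 3.5, source_quote: "Yes (Systolic >=140 mm Hg) ... 3.5"}
  - {factor: physical_activity, level: low,    points: 6, source_quote: "Low ... 6"}
  - {factor: physical_activity, level: medium, points: 0, source_quote: "Medium ... 0"}
  - {factor: physical_activity, level: high,   points: 0, source_quote: "High ... 0"}
  - {factor: sleep_disturbance, level: no,  points: 0,   source_quote: "No ... 0"}
  - {factor: sleep_disturbance, level: yes, points: 3.3, source_quote: "Yes ... 3.3"}
  - {factor: smoking, level: never,   points: 0,   source_quote: "No ... 0"}
  - {factor: smoking, level: former,  points: 0,   source_quote: "Former Smoker ... - (grouped with non-smokers)"}
  - {factor: smoking, level: current, points: 7.9, source_quote: "Yes ... 7.9"}
  - {factor: social_activity, level: lowest,      points: 0,   source_quote: "Lowest ... 0"}
  - {factor: social_activity, level: low_medium,  points: 0,   source_quote: "Low to Medium ... 0"}
  - {factor: social_activity, level: medium_high, points: 0,   source_quote: "Medium to High ... 0"}
  - {factor: social_activity, level: highest,     points: 6.5, source_quote: "Highest ... 6.5 (gradient as printed)"}
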