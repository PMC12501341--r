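# ANU-ADRI weight table. Points per harmonized factor level.
# Pesticide exposure is omitted (no data); demographic entries are the
# sex-specific 5-year age bands and education. source_quote carries the
# verbatim cell text the entry was transcribed from ("-" printed as a dash
# inside a covered factor is transcribed as an explicit 0).
index: ANU-ADRI
source: Table 1
version: 1
entries:
  - {factor: age, level: "<65",   sex: male,   age_min: 0,  age_max: 64,  points: 0,  demographic: true, source_quote: "<65 ... 0"}
  - {factor: age, level: "65-69", sex: male,   age_min: 65, age_max: 69,  points: 1,  demographic: true, source_quote: "65-69 ... 1"}
  - {factor: age, level: "70-74", sex: male,   age_min: 70, age_max: 74,  points: 12, demographic: true, source_quote: "70-74 ... 12"}
  - {factor: age, level: "75-79", sex: male,   age_min: 75, age_max: 79,  points: 18, demographic: true, source_quote: "75-79 ... 18"}
  - {factor: age, level: "80-84", sex: male,   age_min: 80, age_max: 84,  points: 26, demographic: true, source_quote: "80-84 ... 26"}
  - {factor: age, level: "85-89", sex: male,   age_min: 85, age_max: 89,  points: 33, demographic: true, source_quote: "85-89 ... 33"}
  - {factor: age, level: ">90",   sex: male,   age_min: 90, age_max: 200, points: 38, demographic: true, source_quote: ">90 ... 38"}
  - {factor: age, level: "<65",   sex: female, age_min: 0,  age_max: 64,  points: 0,  demographic: true, source_quote: "<65 ... 0"}
  - {factor: age, level: "65-69", sex: female, age_min: 65, age_max: 69,  points: 5,  demographic: true, source_quote: "65-69 ... 5"}
  - {factor: age, level: "70-74", sex: female, age_min: 70, age_max: 74,  points: 14, demographic: true, source_quote: "70-74 ... 14"}
  - {factor: age, level: "75-79", sex: female, age_min: 75, age_max: 79,  points: 21, demographic: true, source_quote: "75-79 ... 21"}
  - {factor: age, level: "80-84", sex: female, age_min: 80, age_max: 84,  points: 29, demographic: true, source_quote: "80-84 ... 29"}
  - {factor: age, level: "85-89", sex: female, age_min: 85, age_max: 89,  points: 35, demographic: true, source_quote: "85-89 ... 35"}
  - {factor: age, level: ">90",   sex: female, age_min: 90, age_max: 200, points: 41, demographic: true, source_quote: ">90 ... 41"}
  - {factor: education, level: low,    points: 0, demographic: true, source_quote: "<8 years / Low ... 0"}
  - {factor: education, level: medium, points: 3, demographic: true, source_quote: "8-11 years / Medium ... 3"}
  - {factor: education, level: high,   points: 6, demographic: true, source_quote: ">11 years / High ... 6"}
  - {factor: alcohol, level: none,         points: 0,  source_quote: "None ... 0"}
  - {factor: alcohol, level: low_moderate, points: -3, source_quote: "Light-Moderate (1-14 units/wk) ... -3"}
  - {factor: alcohol, level: high,         points: 0,  source_quote: "Excessive (>=14 units/wk) ... 0"}
  - {factor: bmi, level: underweight, points: 0, source_quote: "Underweight (<18.5) ... - (dash; transcribed 0)"}
  - {factor: bmi, level: normal,      points: 0, source_quote: "Normal (18.5-24.99) ... 0"}
  - {factor: bmi, level: overweight,  points: 2, source_quote: "Overweight (25-29.99) ... 2"}
  - {factor: bmi, level: obese,       points: 5, source_quote: "Obese (>=30) ... 5"}
  - {factor: cognitive_activity, level: low,    points: 0,  source_quote: "Low ... 0"}
  - {factor: cognitive_activity, level: medium, points: -6, source_quote: "Medium ... -6"}
  - {factor: cognitive_activity, level: high,   points: -7, source_quote: "High ... -7"}
  - {factor: depression, level: no,  points: 0, source_quote: "No ... 0"}
  - {factor: depression, level: yes, points: 2, source_quote: "Yes ... 2"}
  - {factor: diabetes, level: no,  points: 0, source_quote: "No ... 0"}
  - {factor: diabetes, level: yes, points: 3, source_quote: "Yes ... 3"}
  - {factor: fish_intake, level: "0-0.25", points: 0,  source_quote: "0-0.25 servings/week ... 0"}
  - {factor: fish_intake, level: "0.26-2", points: -3, source_quote: "0.26-2 servings/week ... -3"}
  - {factor: fish_intake, level: "2.1-4",  points: -4, source_quote: "2.1-4 servings/week ... -4"}
  - {factor: fish_intake, level: ">4.1",   points: -5, source_quote: ">4.1 servings/week ... -5"}
  - {factor: hypercholesterolemia, level: no,  points: 0, source_quote: "No ... 0"}
  - {factor: hypercholesterolemia, level: yes, points: 3, source_quote: "Yes ... 3"}
  - {factor: physical_activity, level: low,    points: 0,  source_quote: "Low ... 0"}
  - {factor: physical_activity, level: medium, points: -2, source_quote: "Medium ... -2"}
  - {factor: physical_activity, level: high,   points: -3, source_quote: "High ... -3"}
  - {factor: tbi, level: no,  points: 0, source_quote: "No ... 0"}
  - {factor: tbi, level: yes, points: 4, source_quote: "Yes ... 4"}
  - {factor: smoking, level: never,   points: 0, source_quote: "No ... 0"}
  - {factor: smoking, level: former,  points: 1, source_quote: "Former Smoker ... 1"}
  - {factor: smoking, level: current, points: 4, source_quote: "Yes ... 4"}
  - {factor: social_activity, level: lowest,      points: 0, source_quote: "Lowest ... 0"}
  - {factor: social_activity, level: low_medium,  points: 1, source_quote: "Low to Medium ... 1"}
  - {factor: social_activity, level: medium_high, points: 4, source_quote: "Medium to High ... 4"}
  - {factor: social_activity, level: highest,     points: 6, source_quote: "Highest ... 6 (gradient as printed)"}
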