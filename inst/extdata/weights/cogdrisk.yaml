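# CogDrisk weight table. Diabetes is sex-specific (men 2, women 3);
# cognitive activity medium/high are protective (-4 / -5, dashes in the
# printed run-on text read as minus signs -- see the cognitive-activity
# note in the package vignette); former smokers score with never-smokers.
index: CogDrisk
source: Table 1
version: 1
entries:
  - {factor: age, level: "<65",   sex: male,   age_min: 0,  age_max: 64,  points: 0,  demographic: true, source_quote: "<65 ... 0"}
  - {factor: age, level: "65-69", sex: male,   age_min: 65, age_max: 69,  points: 6,  demographic: true, source_quote: "65-69 ... 6"}
  - {factor: age, level: "70-74", sex: male,   age_min: 70, age_max: 74,  points: 8,  demographic: true, source_quote: "70-74 ... 8"}
  - {factor: age, level: "75-79", sex: male,   age_min: 75, age_max: 79,  points: 13, demographic: true, source_quote: "75-79 ... 13"}
  - {factor: age, level: "80-84", sex: male,   age_min: 80, age_max: 84,  points: 17, demographic: true, source_quote: "80-84 ... 17"}
  - {factor: age, level: "85-89", sex: male,   age_min: 85, age_max: 89,  points: 20, demographic: true, source_quote: "85-89 ... 20"}
  - {factor: age, level: ">90",   sex: male,   age_min: 90, age_max: 200, points: 22, demographic: true, source_quote: ">90 ... 22"}
  - {factor: age, level: "<65",   sex: female, age_min: 0,  age_max: 64,  points: 0,  demographic: true, source_quote: "<65 ... 0"}
  - {factor: age, level: "65-69", sex: female, age_min: 65, age_max: 69,  points: 4,  demographic: true, source_quote: "65-69 ... 4"}
  - {factor: age, level: "70-74", sex: female, age_min: 70, age_max: 74,  points: 7,  demographic: true, source_quote: "70-74 ... 7"}
  - {factor: age, level: "75-79", sex: female, age_min: 75, age_max: 79,  points: 11, demographic: true, source_quote: "75-79 ... 11"}
  - {factor: age, level: "80-84", sex: female, age_min: 80, age_max: 84,  points: 15, demographic: true, source_quote: "80-84 ... 15"}
  - {factor: age, level: "85-89", sex: female, age_min: 85, age_max: 89,  points: 19, demographic: true, source_quote: "85-89 ... 19"}
  - {factor: age, level: ">90",   sex: female, age_min: 90, age_max: 200, points: 23, demographic: true, source_quote: ">90 ... 23"}
  - {factor: education, level: low,    points: 4, demographic: true, source_quote: "<8 years / Low ... 4"}
  - {factor: education, level: medium, points: 2, demographic: true, source_quote: "8-11 years / Medium ... 2"}
  - {factor: education, level: high,   points: 0, demographic: true, source_quote: ">11 years / High ... 0"}
  - {factor: bmi, level: underweight, points: 2, source_quote: "Underweight (<18.5) ... 2"}
  - {factor: bmi, level: normal,      points: 0, source_quote: "Normal (18.5-24.99) ... 0"}
  - {factor: bmi, level: overweight,  points: 1, source_quote: "Overweight (25-29.99) ... 1"}
  - {factor: bmi, level: obese,       points: 3, source_quote: "Obese (>=30) ... 3"}
  - {factor: cognitive_activity, level: low,    points: 0,  source_quote: "Low ... 0"}
  - {factor: cognitive_activity, level: medium, points: -4, source_quote: "Medium ... -4 (printed run-on; see vignette)"}
  - {factor: cognitive_activity, level: high,   points: -5, source_quote: "High ... -5 (printed run-on; see vignette)"}
  - {factor: heart_disease, level: no,  points: 0, source_quote: "No ... 0"}
  - {factor: heart_disease, level: yes, points: 2, source_quote: "Yes ... 2"}
  - {factor: depression, level: no,  points: 0, source_quote: "No ... 0"}
  - {factor: depression, level: yes, points: 3, source_quote: "Yes ... 3"}
  - {factor: diabetes, level: no,  sex: male,   points: 0, source_quote: "No ... 0 (M)"}
  - {factor: diabetes, level: yes, sex: male,   points: 2, source_quote: "Yes ... 2 (M)"}
  - {factor: diabetes, level: no,  sex: female, points: 0, source_quote: "No ... 0 (F)"}
  - {factor: diabetes, level: yes, sex: female, points: 3, source_quote: "Yes ... 3 (F)"}
  - {factor: fish_intake, level: "0-0.25", points: 0,     source_quote: "0-0.25 servings/week ... 0"}
  - {factor: fish_intake, level: "0.26-2", points: -0.25, source_quote: "0.26-2 servings/week ... -0.25"}
  - {factor: fish_intake, level: "2.1-4",  points: -0.25, source_quote: "2.1-4 servings/week ... -0.25"}
  - {factor: fish_intake, level: ">4.1",   points: -0.25, source_quote: ">4.1 servings/week ... -0.25"}
  - {factor: hypercholesterolemia, level: no,  points: 0, source_quote: "No ... 0"}
  - {factor: hypercholesterolemia, level: yes, points: 3, source_quote: "Yes ... 3"}
  - {factor: hypertension, level: no,  points: 0, source_quote: "No (Systolic <140 mm Hg) ... 0"}
  - {factor: hypertension, level: yes, points: 1, source_quote: "Yes (Systolic >=140 mm Hg) ... 1"}
  - {factor: physical_activity, level: low,    points: 0,  source_quote: "Low ... 0"}
  - {factor: physical_activity, level: medium, points: -3, source_quote: "Medium ... -3"}
  - {factor: physical_activity, level: high,   points: -3, source_quote: "High ... -3"}
  - {factor: tbi, level: no,  points: 0, source_quote: "No ... 0"}
  - {factor: tbi, level: yes, points: 2, source_quote: "Yes ... 2"}
  - {factor: sleep_disturbance, level: no,  points: 0, source_quote: "No ... 0"}
  - {factor: sleep_disturbance, level: yes, points: 2, source_quote: "Yes ... 2"}
  - {factor: smoking, level: never,   points: 0, source_quote: "No ... 0"}
  - {factor: smoking, level: former,  points: 0, source_quote: "Former Smoker ... - (grouped with non-smokers)"}
  - {factor: smoking, level: current, points: 1, source_quote: "Yes ... 1"}
  - {factor: lonely, level: no,  points: 0, source_quote: "Not Lonely ... 0"}
  - {factor: lonely, level: yes, points: 2, source_quote: "Lonely ... 2"}
  - {factor: stroke, level: no,  points: 0, source_quote: "No ... 0"}
  - {factor: stroke, level: yes, points: 2, source_quote: "Yes ... 2"}
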