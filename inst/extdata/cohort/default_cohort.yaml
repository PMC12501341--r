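# Default synthetic-cohort calibration.
#
# Level counts are the included ("analytic") and excluded ("missing")
# participant profiles of the source cohort's descriptive table; generator
# prevalences are derived as included counts / column total. Cognitive and
# social activity are cohort-relative composites (tertiles / quartiles by
# construction) and therefore carry no prevalence entries here.
n_participants: 5247
n_excluded: 4479
female_fraction: 0.528
age_mean: 66.6
age_sd: 5.8
age_range: [57.8, 90.0]
followup_offset_mean: 10.6
dementia_prevalence: 0.108
ad_fraction_of_dementia: 0.5795   # 328 AD / 566 dementia cases
mci_fraction_amnestic: 0.12       # of non-dementia participants
mci_fraction_nonamnestic: 0.08
apoe_homozygote_fraction: 0.0987  # 138 / 1399 carriers

factor_levels:
  education:            [low, medium, high]
  alcohol:              [none, low_moderate, high]
  apoe4:                [non_carrier, carrier]
  bmi:                  [underweight, normal, overweight, obese]
  heart_disease:        [no, yes]
  depression:           [no, yes]
  diabetes:             [no, yes]
  fish_intake:          ["0-0.25", "0.26-2", "2.1-4", ">4.1"]
  mediterranean_diet:   [yes, no]
  hearing:              [no, yes]
  hypercholesterolemia: [no, yes]
  hypertension:         [no, yes]
  physical_activity:    [low, medium, high]
  tbi:                  [no, yes]
  sleep_disturbance:    [no, yes]
  smoking:              [never, former, current]
  lonely:               [no, yes]
  stroke:               [no, yes]

counts_included:
  sex:                  {female: 2768, male: 2479}
  dementia:             {no_dementia: 4681, dementia: 566}
  education:            {low: 3, medium: 3376, high: 1868}
  alcohol:              {none: 3924, low_moderate: 1295, high: 28}
  apoe4:                {non_carrier: 3848, carrier: 1399}
  bmi:                  {underweight: 21, normal: 1272, overweight: 2662, obese: 1292}
  cognitive_activity:   {low: 1428, medium: 1874, high: 1945}
  heart_disease:        {no: 4376, yes: 871}
  depression:           {no: 4733, yes: 514}
  diabetes:             {no: 4804, yes: 443}
  fish_intake:          {"0-0.25": 1205, "0.26-2": 3600, "2.1-4": 321, ">4.1": 121}
  mediterranean_diet:   {yes: 3031, no: 2216}
  hearing:              {no: 2882, yes: 2365}
  hypercholesterolemia: {no: 3928, yes: 1319}
  hypertension:         {no: 2788, yes: 2459}
  physical_activity:    {low: 943, medium: 42, high: 4262}
  tbi:                  {no: 4906, yes: 341}
  sleep_disturbance:    {no: 3590, yes: 1657}
  smoking:              {never: 2216, former: 2224, current: 807}
  social_activity:      {lowest: 1245, low_medium: 1344, medium_high: 1344, highest: 1314}
  lonely:               {no: 4302, yes: 945}
  stroke:               {no: 5044, yes: 203}

counts_excluded:
  sex:                  {female: 2525, male: 1954}
  dementia:             {no_dementia: 3538, dementia: 941}
  education:            {low: 2, medium: 3172, high: 1305}
  alcohol:              {none: 1710, low_moderate: 711, high: 26}
  apoe4:                {non_carrier: 3183, carrier: 1195}
  bmi:                  {underweight: 9, normal: 780, overweight: 1545, obese: 777}
  cognitive_activity:   {low: 941, medium: 743, high: 524}
  heart_disease:        {no: 3802, yes: 677}
  depression:           {no: 4224, yes: 255}
  diabetes:             {no: 4040, yes: 439}
  fish_intake:          {"0-0.25": 569, "0.26-2": 1993, "2.1-4": 245, ">4.1": 93}
  mediterranean_diet:   {yes: 1621, no: 1278}
  hearing:              {no: 2795, yes: 1684}
  hypercholesterolemia: {no: 2213, yes: 746}
  hypertension:         {no: 1624, yes: 2855}
  physical_activity:    {low: 464, medium: 23, high: 1388}
  tbi:                  {no: 4201, yes: 278}
  sleep_disturbance:    {no: 1472, yes: 713}
  smoking:              {never: 1197, former: 1179, current: 492}
  social_activity:      {lowest: 604, low_medium: 576, medium_high: 630, highest: 602}
  lonely:               {no: 2002, yes: 521}
  stroke:               {no: 3011, yes: 132}

# Sample-flow counts of the source design (eligible follow-up sample,
# baseline participants among them, analytic sample after complete-case
# exclusion, and non-AD dementia cases dropped from the AD sub-analysis).
sample_flow:
  followup_participants: 9930
  outcome_classified: 9726
  baseline_participants: 8397
  analytic_sample: 5247
  non_ad_dementia_cases: 238

# Latent correlations among the age latent and factor latents (pairs not
# listed are 0). Factor latents are oriented so that a larger value means a
# later level in the factor_levels order above.
latent_correlation:
  - [age, hypertension, 0.30]
  - [age, hearing, 0.45]
  - [age, diabetes, 0.15]
  - [age, heart_disease, 0.25]
  - [age, stroke, 0.20]
  - [age, hypercholesterolemia, 0.10]
  - [age, physical_activity, -0.15]
  - [age, cognitive_activity, -0.20]
  - [age, smoking, -0.10]
  - [hypertension, heart_disease, 0.20]
  - [diabetes, bmi, 0.25]
  - [hypertension, bmi, 0.20]
  - [depression, lonely, 0.35]
  - [depression, sleep_disturbance, 0.30]
  - [lonely, social_activity, -0.35]
  - [cognitive_activity, social_activity, 0.25]
  - [mediterranean_diet, fish_intake, -0.20]
  - [physical_activity, bmi, -0.15]

# Baseline log-odds coefficients of the outcome model. `age` is per year,
# `education` per ordered level (low=1 ... high=3); factor terms apply to
# the named risk level. The intercept is calibrated at generation time so
# the realized prevalence matches dementia_prevalence.
outcome_model:
  target_prevalence: 0.108
  coefficients:
    age: 0.148
    education: -0.478
  factor_effects:
    apoe4:                {level: carrier, beta: 0.80}
    smoking:              {level: current, beta: 0.30}
    diabetes:             {level: yes, beta: 0.40}
    depression:           {level: yes, beta: 0.40}
    hypertension:         {level: yes, beta: 0.20}
    physical_activity:    {level: low, beta: 0.30}
    hearing:              {level: yes, beta: 0.30}
    stroke:               {level: yes, beta: 0.50}
    heart_disease:        {level: yes, beta: 0.20}
    lonely:               {level: yes, beta: 0.30}
    sleep_disturbance:    {level: yes, beta: 0.15}
    bmi:                  {level: obese, beta: 0.15}
    hypercholesterolemia: {level: yes, beta: 0.10}
    alcohol:              {level: high, beta: 0.30}
    cognitive_activity:   {level: low, beta: 0.30}
    social_activity:      {level: lowest, beta: 0.25}
    fish_intake:          {level: "0-0.25", beta: 0.15}
    tbi:                  {level: yes, beta: 0.30}
    mediterranean_diet:   {level: no, beta: 0.15}

# MAR missingness defaults: per-variable logistic log-odds on baseline age
# (per year, centered at 66.6), female sex, and education level (1-3).
# Calibrated so that overall per-variable missingness is roughly 10-20% and
# missing participants are older, more often female, and less educated.
missingness_model:
  default: {intercept: -2.0, age: 0.06, female: 0.25, education: -0.30}
  variables:
    height: {intercept: -2.2, age: 0.05, female: 0.2, education: -0.2}
    weight: {intercept: -2.2, age: 0.05, female: 0.2, education: -0.2}
    systolic_bp_2nd: {intercept: -1.8, age: 0.07, female: 0.25, education: -0.3}
    systolic_bp_3rd: {intercept: -1.8, age: 0.07, female: 0.25, education: -0.3}
    total_cholesterol: {intercept: -2.0, age: 0.05, female: 0.2, education: -0.25}
    hads_depression: {intercept: -1.7, age: 0.08, female: 0.3, education: -0.35}
    alcohol_units_per_week: {intercept: -1.9, age: 0.06, female: 0.3, education: -0.3}
    smoking: {intercept: -2.3, age: 0.05, female: 0.2, education: -0.2}
    mvpa_minutes_per_week: {intercept: -1.6, age: 0.08, female: 0.25, education: -0.35}
    apoe_e4_count: {intercept: -2.5, age: 0.02, female: 0.0, education: 0.0}
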