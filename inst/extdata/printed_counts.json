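{
  "comment": "Published summary counts for hypertriglyceridemia online-consultation cohorts, used only for arithmetic consistency checks. Checks with expect_pass=false record printed values that are internally inconsistent.",
  "checks": [
    {"name": "tg_only_edge_pct", "type": "percent", "numerator": 4788, "denominator": 26603, "decimals": 1, "expected": 18.0},
    {"name": "tg_only_mild_pct", "type": "percent", "numerator": 13994, "denominator": 26603, "decimals": 1, "expected": 52.6},
    {"name": "tg_only_severe_pct", "type": "percent", "numerator": 7821, "denominator": 26603, "decimals": 1, "expected": 29.4},
    {"name": "tg_chol_edge_pct", "type": "percent", "numerator": 2225, "denominator": 9691, "decimals": 1, "expected": 23.0},
    {"name": "tg_chol_mild_pct", "type": "percent", "numerator": 4989, "denominator": 9691, "decimals": 1, "expected": 51.5},
    {"name": "tg_chol_severe_pct", "type": "percent", "numerator": 2477, "denominator": 9691, "decimals": 1, "expected": 25.6},
    {"name": "preg_tg_only_edge_pct", "type": "percent", "numerator": 27, "denominator": 244, "decimals": 1, "expected": 11.1},
    {"name": "preg_tg_only_mild_pct", "type": "percent", "numerator": 134, "denominator": 244, "decimals": 1, "expected": 54.9},
    {"name": "preg_tg_only_severe_pct", "type": "percent", "numerator": 83, "denominator": 244, "decimals": 1, "expected": 34.0},
    {"name": "preg_tg_chol_edge_pct", "type": "percent", "numerator": 25, "denominator": 162, "decimals": 1, "expected": 15.4},
    {"name": "preg_tg_chol_mild_pct", "type": "percent", "numerator": 94, "denominator": 162, "decimals": 1, "expected": 58.0},
    {"name": "preg_tg_chol_severe_pct", "type": "percent", "numerator": 43, "denominator": 162, "decimals": 1, "expected": 26.5},
    {"name": "total_edge_pct", "type": "percent", "numerator": 7013, "denominator": 36294, "decimals": 1, "expected": 19.3},
    {"name": "total_mild_pct", "type": "percent", "numerator": 18983, "denominator": 36294, "decimals": 1, "expected": 52.3},
    {"name": "total_severe_pct", "type": "percent", "numerator": 10298, "denominator": 36294, "decimals": 1, "expected": 28.4},
    {"name": "male_share_pct", "type": "percent", "numerator": 7495, "denominator": 13155, "decimals": 2, "expected": 56.97},
    {"name": "female_share_pct", "type": "percent", "numerator": 5660, "denominator": 13155, "decimals": 2, "expected": 43.03},
    {"name": "pregnancy_share_pct", "type": "percent", "numerator": 895, "denominator": 5660, "decimals": 1, "expected": 15.8},
    {"name": "tg_only_share_pct", "type": "percent", "numerator": 26603, "denominator": 36294, "decimals": 1, "expected": 73.3},
    {"name": "tg_chol_share_pct_printed", "type": "percent", "numerator": 9691, "denominator": 36294, "decimals": 1, "expected": 16.7, "expect_pass": false},
    {"name": "edge_total_additivity", "type": "sum", "parts": [4788, 2225], "expected": 7013},
    {"name": "mild_total_additivity", "type": "sum", "parts": [13994, 4989], "expected": 18983},
    {"name": "severe_total_additivity", "type": "sum", "parts": [7821, 2477], "expected": 10298},
    {"name": "cohort_total_additivity", "type": "sum", "parts": [26603, 9691], "expected": 36294},
    {"name": "tg_only_internal_sum", "type": "sum", "parts": [4788, 13994, 7821], "expected": 26603},
    {"name": "tg_chol_internal_sum", "type": "sum", "parts": [2225, 4989, 2477], "expected": 9691},
    {"name": "preg_tg_only_internal_sum", "type": "sum", "parts": [27, 134, 83], "expected": 244},
    {"name": "preg_tg_chol_internal_sum", "type": "sum", "parts": [25, 94, 43], "expected": 162},
    {"name": "gender_total_sum", "type": "sum", "parts": [7495, 5660], "expected": 13155},
    {"name": "response_total_sum", "type": "sum", "parts": [61677, 50086], "expected": 111763},
    {"name": "lifestyle_smoking_pct", "type": "percent", "numerator": 130, "denominator": 1259, "decimals": 1, "expected": 10.3},
    {"name": "lifestyle_weight_pct", "type": "percent", "numerator": 155, "denominator": 1259, "decimals": 1, "expected": 12.3},
    {"name": "lifestyle_exercise_pct", "type": "percent", "numerator": 414, "denominator": 1259, "decimals": 1, "expected": 32.8, "expect_pass": false},
    {"name": "lifestyle_carb_pct", "type": "percent", "numerator": 96, "denominator": 1259, "decimals": 1, "expected": 7.6},
    {"name": "lifestyle_alcohol_pct", "type": "percent", "numerator": 148, "denominator": 1259, "decimals": 1, "expected": 11.8},
    {"name": "lifestyle_oil_pct", "type": "percent", "numerator": 277, "denominator": 1259, "decimals": 1, "expected": 22.0},
    {"name": "lifestyle_diet_pct", "type": "percent", "numerator": 657, "denominator": 1259, "decimals": 1, "expected": 52.2},
    {"name": "drug_combo_pct", "type": "percent", "numerator": 275, "denominator": 6746, "decimals": 1, "expected": 4.1},
    {"name": "drug_niacin_pct", "type": "percent", "numerator": 146, "denominator": 6746, "decimals": 1, "expected": 2.2},
    {"name": "drug_tcm_pct", "type": "percent", "numerator": 1214, "denominator": 6746, "decimals": 1, "expected": 18.0},
    {"name": "drug_statin_pct", "type": "percent", "numerator": 2889, "denominator": 6746, "decimals": 1, "expected": 42.8},
    {"name": "drug_fibrate_pct", "type": "percent", "numerator": 3327, "denominator": 6746, "decimals": 1, "expected": 49.3},
    {"name": "drug_other_pct", "type": "percent", "numerator": 148, "denominator": 6746, "decimals": 1, "expected": 2.2},
    {"name": "combo_two_pct", "type": "percent", "numerator": 236, "denominator": 275, "decimals": 1, "expected": 85.8},
    {"name": "combo_three_pct", "type": "percent", "numerator": 39, "denominator": 275, "decimals": 1, "expected": 14.2},
    {"name": "factor_economics_pct", "type": "percent", "numerator": 30, "denominator": 2704, "decimals": 1, "expected": 1.1},
    {"name": "factor_brand_pct", "type": "percent", "numerator": 31, "denominator": 2704, "decimals": 1, "expected": 1.1},
    {"name": "factor_tcm_pct", "type": "percent", "numerator": 470, "denominator": 2704, "decimals": 1, "expected": 17.4},
    {"name": "factor_effectiveness_pct", "type": "percent", "numerator": 1190, "denominator": 2704, "decimals": 1, "expected": 44.0},
    {"name": "factor_safety_pct", "type": "percent", "numerator": 1393, "denominator": 2704, "decimals": 1, "expected": 51.5},
    {"name": "consult_response_rate", "type": "rate", "numerator": 61677, "denominator": 32827.15, "expected": 1.88, "tolerance": 0.02},
    {"name": "qa_response_rate", "type": "rate", "numerator": 50086, "denominator": 37017.85, "expected": 1.34, "tolerance": 0.02}
  ]
}
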