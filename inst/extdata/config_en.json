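{
  "language": "en",
  "severity_cutpoints": {"edge": 1.7, "mild_moderate": 2.3, "severe": 5.6},
  "demands": [
    {"label": "how_to_treat", "rank": 1, "group": "how_to_intervene",
     "phrases": ["how to treat", "how to do", "what should i do"]},
    {"label": "drug_selection", "rank": 2, "group": "drug_intervention",
     "phrases": ["what drug", "which drug", "what medicine"]},
    {"label": "disease_concepts", "rank": 3, "group": "disease_cognition",
     "phrases": ["what are triglycerides", "what is hyperlipidemia", "what does triglyceride mean"]},
    {"label": "lifestyle_precautions", "rank": 4, "group": "lifestyle_intervention",
     "phrases": ["what to pay attention to", "precautions in daily life"]},
    {"label": "disease_causes", "rank": 5, "group": "disease_cognition",
     "phrases": ["what causes", "is it hereditary"]},
    {"label": "medication", "rank": 6, "group": "drug_intervention",
     "phrases": ["need medication", "do i need medicine", "should i start medicine"]},
    {"label": "dietary_control", "rank": 7, "group": "lifestyle_intervention",
     "phrases": ["how to control my diet", "what can i not eat"]},
    {"label": "lipid_lowering_foods", "rank": 8, "group": "lifestyle_intervention",
     "phrases": ["what foods to eat to reduce", "which foods lower"]},
    {"label": "disease_impact", "rank": 9, "group": "disease_cognition",
     "phrases": ["what hazards", "what harm"]},
    {"label": "diagnosis_treatment_criteria", "rank": 10, "group": "disease_cognition",
     "phrases": ["how serious", "how severe"]}
  ],
  "relations": {
    "father": "male", "husband": "male", "brother": "male", "son": "male",
    "grandfather": "male", "uncle": "male",
    "mother": "female", "wife": "female", "sister": "female",
    "daughter": "female", "grandmother": "female", "aunt": "female",
    "parent": "unknown", "spouse": "unknown", "relative": "unknown",
    "friend": "unknown"
  },
  "gender_direct": {
    "female": ["i am a woman", "i am female", "year old woman", "year-old woman"],
    "male": ["i am a man", "i am male", "year old man", "year-old man"]
  },
  "age_indirect": {
    "in my teens": 16, "in my twenties": 25, "in my thirties": 35,
    "in my forties": 45, "in my fifties": 55, "in my sixties": 65,
    "over sixty": 65, "over seventy": 75
  },
  "pregnancy_terms": ["pregnant", "pregnancy", "gestation"],
  "symptoms": {
    "head": ["dizziness", "dizzy", "headache"],
    "chest": ["chest tightness", "chest pain", "palpitation", "shortness of breath"],
    "other": ["fatigue", "blurred vision", "numbness"]
  },
  "secondary": {
    "ascvd_cardiac": ["coronary heart disease", "myocardial infarction"],
    "ascvd_cerebral": ["cerebral infarction", "stroke"],
    "pancreatitis": ["pancreatitis"]
  },
  "lifestyle_current": {
    "smoking_cessation": ["quit smoking", "stopped smoking"],
    "weight_control": ["lose weight", "losing weight", "control my weight"],
    "exercise": ["exercise", "jogging"],
    "limit_carbohydrate": ["limit carbohydrate", "cut down on carbohydrate"],
    "limit_alcohol": ["limit alcohol", "stopped drinking alcohol"],
    "limit_oil": ["less oil", "limit oil"],
    "diet_control": ["strict diet", "watching what i eat"]
  },
  "drug_classes": {
    "fibrate": ["fenofibrate", "bezafibrate", "lipanthyl", "fibrate"],
    "statin": ["lovastatin", "simvastatin", "pravastatin", "fluvastatin", "atorvastatin", "rosuvastatin", "pitavastatin", "statin"],
    "tcm": ["xuezhikang", "zhibituo", "zhikening"],
    "niacin": ["niacin", "nicotinic acid"],
    "fish_oil": ["fish oil"],
    "other": ["ezetimibe", "probucol"]
  },
  "selection_factors": {
    "safety": ["safe", "safety", "side effect"],
    "effectiveness": ["effective", "efficacy", "does it work"],
    "economics": ["expensive", "cheap", "cost"],
    "brand": ["brand"],
    "tcm_preference": ["prefer traditional chinese medicine", "prefer chinese medicine"]
  },
  "response_lifestyle": {
    "reduce_fats": ["reduce fat", "less fatty food", "restrict fat intake"],
    "exercise": ["exercise"],
    "smoking_cessation": ["quit smoking"],
    "weight_control": ["lose weight", "control weight"],
    "limit_carbohydrate": ["limit carbohydrate", "restrict carbohydrate"],
    "limit_alcohol": ["limit alcohol", "restrict alcohol"],
    "limit_oil": ["less oil", "limit oil"]
  },
  "diet_control_phrases": ["control your diet", "diet control"],
  "supplement_terms": ["supplement", "health products"],
  "lipid_lowering_diet_terms": ["lipid-lowering diet"],
  "cholesterol_elevated_patterns": ["cholesterol is also high", "cholesterol is high", "high cholesterol", "elevated cholesterol", "cholesterol is elevated"],
  "link_tokens": ["http://", "https://", "www.", "click the link"],
  "promo_markers": ["join our group", "special offer", "our clinic offers", "add our consultation"],
  "science_markers": ["are a type of", "is a type of", "refers to", "is defined as", "popular science", "encyclopedia", "health knowledge:"],
  "illness_patterns": ["(my|his|her) [^.?!]{0,40}(triglyceride|tg|lipid|cholesterol)", "(my|his|her) [^.?!]{0,30}(level|value|result)", "(my|his|her) [a-z]+ (is|was|has|had|took|takes|feels)", "i (have|had|feel|am)"],
  "stoplist": ["tg"]
}
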