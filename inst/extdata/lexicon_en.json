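{
  "language": "en",
  "I-a": ["hypertriglyceridemia", "high tg", "high triglyceride", "mixed hyperlipidemia"],
  "I-b": ["hyperlipidemia", "dyslipidemia", "thick blood lipids", "three high"],
  "II-a": ["triglyceride", "triglycerides", "triacylglycerol", "triacylglycerols", "tg"],
  "II-b": ["blood lipid", "blood lipids"],
  "III": ["diet", "food"],
  "IV-a": ["fibrate", "fenofibrate", "lipanthyl", "bezafibrate"],
  "IV-b": ["statin", "statins", "lipid-lowering drug", "lovastatin", "simvastatin", "pravastatin", "fluvastatin", "atorvastatin", "rosuvastatin", "pitavastatin", "niacin", "ezetimibe", "probucol", "fish oil", "xuezhikang", "zhibituo", "zhikening"]
}
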