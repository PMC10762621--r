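text|is_ad|is_science
click http://miracle.example for miracle lipid cure|TRUE|FALSE
special offer: buy fenofibrate at a discount at www.pharmadeal.example|TRUE|FALSE
join our group for daily blood lipid tips|TRUE|FALSE
our clinic offers free triglyceride testing, click the link to book|TRUE|FALSE
best prices on statins at https://cheapmeds.example|TRUE|FALSE
add our consultation service for vip lipid management|TRUE|FALSE
discount fish oil capsules, visit www.supplestore.example|TRUE|FALSE
visit http://lipidcenter.example the top hospital for hyperlipidemia|TRUE|FALSE
special offer on bezafibrate, click the link now|TRUE|FALSE
www.tcmshop.example sells xuezhikang cheap, join our group|TRUE|FALSE
my tg is 3.1 mmol/l, see http://report-link.example|FALSE|FALSE
i have dizziness and my doctor sent me www.advice.example|FALSE|FALSE
her triglyceride is 4.2, the lab report is at https://lab.example|FALSE|FALSE
no links here, my triglyceride is 2.0 mmol/l|FALSE|FALSE
i am a 40 year old man, my tg came back 200 mg/dl, what should i do|FALSE|FALSE
chest pain after dinner, found www.heartinfo.example unhelpful|FALSE|FALSE
my father took fenofibrate, is www.druginfo.example reliable|FALSE|FALSE
i have high tg and someone sent a special offer, should i trust it|FALSE|FALSE
triglycerides are a type of blood fat found in the body|FALSE|TRUE
hypertriglyceridemia refers to an elevated level of triglycerides in plasma|FALSE|TRUE
popular science: how diet affects blood lipid levels|FALSE|TRUE
hyperlipidemia is defined as abnormally elevated lipids in blood|FALSE|TRUE
encyclopedia entry: triglyceride metabolism and the liver|FALSE|TRUE
fish oil is a type of supplement often discussed for lipid control|FALSE|TRUE
health knowledge: what the tg index on a lab sheet means|FALSE|TRUE
a statin is a type of drug that lowers cholesterol in the population|FALSE|TRUE
dietary fat refers to triacylglycerols consumed with food|FALSE|TRUE
popular science: exercise and blood lipid, a short explainer|FALSE|TRUE
triglycerides are a type of blood fat. my level is 2.8|FALSE|FALSE
my doctor says triglycerides are a type of blood fat, mine is 5.0 mmol/l|FALSE|FALSE
hyperlipidemia refers to high lipids, and his tg is 6.1 mmol/l|FALSE|FALSE
i have read that tg refers to triglyceride, my result is 3.3|FALSE|FALSE
i am a 30 year old woman, my triglyceride is 2.1 mmol/l, how to treat|FALSE|FALSE
my mother is 62 years old, her tg is 5.9 mmol/l, what drug|FALSE|FALSE
tg 9.0 mmol/l with pancreatitis, need medication|FALSE|FALSE
my husband has chest tightness, tg 4.4, is it serious|FALSE|FALSE
i quit smoking and my blood lipid improved, tg now 1.9|FALSE|FALSE
my triglyceride was 1.5 then 2.4 mmol/l, what causes this|FALSE|FALSE
28 weeks pregnant, tg 3.9 mmol/l, worried about the baby|FALSE|FALSE
my wife is in her thirties, her triglyceride is 2.6, what to pay attention to|FALSE|FALSE
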