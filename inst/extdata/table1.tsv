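drug	indication	stage	target	actions	direction	evidence
Erythromycin	Respiratory tract infections	Recruiting	CYP3A7	Inhibitor	GOF	NA
Milrinone	Congestive heart failure	Recruiting	PDE3A	Inhibitor	GOF	Murata et al.
Dapsone	Leprosy and dermatitis herpetiformis	Completed	CYP3A7	Substrate	LOF	Kyllo et al.
Dapsone	Leprosy and dermatitis herpetiformis	Completed	NAT2	Substrate	LOF	Kyllo et al.
Theophylline	Chronic asthma	NA	CYP1A2	Inhibitor|Substrate	GOF	Steinberg and Whittaker; Wick
Theophylline	Chronic asthma	NA	CYP1B1	Inhibitor|Substrate	GOF	Steinberg and Whittaker; Wick
Theophylline	Chronic asthma	NA	CYP2D6	Inhibitor|Substrate	GOF	Steinberg and Whittaker; Wick
Theophylline	Chronic asthma	NA	PDE3A	Inhibitor|Substrate	GOF	Steinberg and Whittaker; Wick
Gefitinib	Metastatic nonsmall cell lung cancer	Completed	CYP1A1	Antagonist	GOF	Djerf et al.
Gefitinib	Metastatic nonsmall cell lung cancer	Completed	EGFR	Antagonist	GOF	Djerf et al.
Omeprazole	Duodenal ulcers	Completed	ABCC3	Inducer	LOF	Matsui et al.
Omeprazole	Duodenal ulcers	Completed	CYP1A1	Inducer	LOF	Matsui et al.
Omeprazole	Duodenal ulcers	Completed	CYP1A2	Inducer	LOF	Matsui et al.
Levonorgestrel	Enopausal and postmenopausal disorders	Completed	CYP19A1	Inhibitor	GOF	Kjaeldgaard et al.
Levonorgestrel	Enopausal and postmenopausal disorders	Completed	ESR1	Inhibitor	GOF	Kjaeldgaard et al.
Mexiletine	Ventricular fibrillation	Completed	CYP1A2	Inhibitor	LOF	Kuraishi et al.; Andoh et al.
Rosiglitazone	Type 2 diabetes mellitus	Completed	CYP2A6	Inhibitor	GOF	Mossner et al.
Chloramphenicol	Etracycline-resistant vibrios	Recruiting	CYP3A7	Inhibitor	GOF	Lamb et al.
Buspirone	Anxiety disorders	Completed	CYP3A7	Substrate	LOF	NA
Zidovudine	Human immunovirus infections	Completed	CYP2A6	Substrate|Inhibitor	GOF	Fang and Beland
Zidovudine	Human immunovirus infections	Completed	TERT	Substrate|Inhibitor	GOF	Fang and Beland
Flutamide	Prostate cancer	Completed	CYP1B1	Substrate|Inhibitor	GOF	Hsueh et al.
Cimetidine	Peptic ulcer disease	Completed	SLC22A5	Inhibitor	GOF	Flodgren et al.; Harland and Saihan
Cimetidine	Peptic ulcer disease	Completed	CYP3A7	Inhibitor	GOF	Flodgren et al.; Harland and Saihan
Diclofenac	Osteoarthritis and rheumatoid arthritis	Completed	PLA2G2A	Inhibitor	GOF	Albano et al.
Monobenzone	Skin vitiligo	NA	TYR	Inhibitor	GOF	van den Boorn et al.
Trazodone	Depression	Completed	CYP3A7	Substrate	LOF	Chang and Lin
Verapamil	Hypertension, angina, and cluster headache	Completed	SLC22A5	Inhibitor	GOF	Robinson et al.; Formelli et al.
Cefixime	Various infections	Completed	SLC22A5	Inhibitor	GOF	NA
Flurbiprofen	Osteoarthritis and ankylosing spondylitis	Completed	UGT1A1	Inhibitor	GOF	NA
Norethisterone	Dysfunctional Uterine Bleeding	Completed	CYP3A7	Substrate	LOF	Kjaeldgaard et al.
Risperidone	Schizophrenic disorders	Completed	CYP3A7	Substrate	LOF	Uzawa et al.
Hydrocortisone	Acute Gouty Arthritis	Completed	CYP3A7	Substrate	LOF	Wang et al.; Rathore et al.
Estradiol	Vasomotor symptoms	Completed	CYP1B1	Agonist	LOF	Kanda and Watanabe; Poletini et al.; Li et al.
Estradiol	Vasomotor symptoms	Completed	CYP2C8	Agonist	LOF	Kanda and Watanabe; Poletini et al.; Li et al.
Estradiol	Vasomotor symptoms	Completed	CYP3A7	Agonist	LOF	Kanda and Watanabe; Poletini et al.; Li et al.
Estradiol	Vasomotor symptoms	Completed	UGT1A1	Agonist	LOF	Kanda and Watanabe; Poletini et al.; Li et al.
Estradiol	Vasomotor symptoms	Completed	ESR1	Agonist	LOF	Kanda and Watanabe; Poletini et al.; Li et al.
Tacrolimus	Heart Transplant Rejection	Completed	CYP3A7	Substrate	LOF	Matsumoto et al.; Puza et al.
Zalcitabine	Human Immunodeficiency Virus	Completed	DCK	Substrate	GOF	Hardeman et al.
Acetylsalicylic acid	Moderate Pain	Completed	EDNRA	Inhibitor	GOF	Kumar et al.
Rifampicin	Tuberculosis	Completed	ABCC3	Inducer|Inhibitor	GOF	Levavasseur et al.
Rifampicin	Tuberculosis	Completed	CYP2A6	Inducer|Inhibitor	GOF	Levavasseur et al.
Praziquantel	Schistosoma infection	Completed	CYP3A7	Substrate	LOF	NA
Norfloxacin	Urinary tract infection	Recruiting	SLC22A5	Inhibitor	GOF	Gouvea et al.
Norfloxacin	Urinary tract infection	Recruiting	CYP3A7	Inhibitor	GOF	Gouvea et al.
Amiodarone	Recurrent ventricular fibrillation	Completed	CYP2A6	Inhibitor	GOF	Zuba et al.
Amiodarone	Recurrent ventricular fibrillation	Completed	CYP3A7	Inhibitor	GOF	Zuba et al.
Bupropion	Depression, Bipolar	Completed	CYP2A6	Substrate	LOF	Ashrafi et al.
Mitoxantrone	Progressive relapsing	Completed	CYP1B1	Inhibitor	GOF	Yu et al.
Saquinavir	Human Immunodeficiency Virus	Completed	CYP3A7	Substrate	LOF	Mijatovic et al.; Donia et al.
Clomipramine	Obsessive Compulsive Disorder	Completed	GSTP1	Inhibitor	GOF	Parker et al.
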