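concept_id	category	preferred_term	synonyms
SCT:3006004	medical_problem	disturbance of consciousness	disturbance of consciousness|impaired consciousness
SCT:42842009	medical_problem	cardiac murmur	cardiac murmur|heart murmur
SCT:246116008	observable	lesion size	lesion size
RID3277	medical_problem	ventricular septal defect	ventricular septal defect|vsd
SYN:MP001	medical_problem	fever	fever|pyrexia
SYN:MP002	medical_problem	cough	cough
SYN:MP003	medical_problem	feeding difficulty	feeding difficulty|poor feeding
SYN:MP004	medical_problem	failure to thrive	failure to thrive
SYN:MP005	medical_problem	recurrent respiratory infection	recurrent respiratory infection
SYN:MP006	medical_problem	lower limb edema	lower limb edema
SYN:MP007	medical_problem	chest pain	chest pain
SYN:MP008	medical_problem	syncope	syncope|fainting
SYN:MP009	medical_problem	hepatomegaly	hepatomegaly|enlarged liver
SYN:MP010	medical_problem	wheezing	wheezing|wheeze
SYN:MP011	medical_problem	poor appetite	poor appetite
SYN:MP012	medical_problem	vomiting	vomiting|emesis
SYN:MP013	medical_problem	diarrhea	diarrhea
SYN:MP014	medical_problem	lethargy	lethargy
SYN:MP015	medical_problem	rhinorrhea	rhinorrhea|runny nose
SYN:MP016	medical_problem	sore throat	sore throat
SYN:MP020	medical_problem	atrial septal defect	atrial septal defect|asd
SYN:MP021	medical_problem	patent ductus arteriosus	patent ductus arteriosus|pda
SYN:MP022	medical_problem	patent foramen ovale	patent foramen ovale|pfo
SYN:MP023	medical_problem	tricuspid regurgitation	tricuspid regurgitation
SYN:MP024	medical_problem	mitral regurgitation	mitral regurgitation
SYN:MP025	medical_problem	pulmonary hypertension	pulmonary hypertension
SYN:MP026	medical_problem	left atrial enlargement	left atrial enlargement
SYN:MP027	medical_problem	pericardial effusion	pericardial effusion
SYN:MP028	medical_problem	aortic coarctation	aortic coarctation
SYN:MP029	medical_problem	right ventricular hypertrophy	right ventricular hypertrophy
SYN:MP030	medical_problem	patchy infiltration	patchy infiltration
SYN:MP031	medical_problem	lobar consolidation	lobar consolidation
SYN:MP032	medical_problem	pleural effusion	pleural effusion
SYN:MP033	medical_problem	hilar lymphadenopathy	hilar lymphadenopathy
SYN:MP034	medical_problem	atelectasis	atelectasis
SYN:MP035	medical_problem	pneumothorax	pneumothorax
SYN:MP036	medical_problem	bronchial wall thickening	bronchial wall thickening
SYN:MP037	medical_problem	increased lung markings	increased lung markings
SYN:MP038	medical_problem	cardiomegaly	cardiomegaly|enlarged heart
SYN:MP039	medical_problem	interstitial infiltration	interstitial infiltration
SYN:MP040	medical_problem	cyanosis	cyanosis
SYN:MP041	medical_problem	dyspnea	dyspnea|shortness of breath
SYN:MP042	medical_problem	diaphoresis	diaphoresis|excessive sweating
SYN:MP043	medical_problem	palpitations	palpitations
SYN:MP044	medical_problem	fatigue	fatigue
SYN:MP045	medical_problem	hemoptysis	hemoptysis
SYN:MP046	medical_problem	night sweats	night sweats
SYN:MP047	medical_problem	chills	chills|rigors
SYN:MP048	medical_problem	tuberculosis exposure	tuberculosis exposure
SYN:MP049	medical_problem	influenza contact	influenza contact
SYN:MP050	medical_problem	allergic rhinitis	allergic rhinitis
SYN:MP060	medical_problem	left ventricular dysfunction	left ventricular dysfunction
SYN:MP061	medical_problem	pulmonary valve stenosis	pulmonary valve stenosis
SYN:MP062	medical_problem	aortic dilatation	aortic dilatation
SYN:TR001	treatment	digoxin	digoxin
SYN:TR002	treatment	furosemide	furosemide
SYN:TR003	treatment	captopril	captopril
SYN:TR004	treatment	azithromycin	azithromycin
SYN:TR005	treatment	amoxicillin	amoxicillin
SYN:TR006	treatment	oseltamivir	oseltamivir
SYN:TE001	test	echocardiography	echocardiography|cardiac ultrasound
SYN:TE002	test	electrocardiogram	electrocardiogram|ecg
SYN:TE003	test	chest radiograph	chest radiograph|chest x ray
SYN:TE004	test	sputum culture	sputum culture
SYN:TE005	test	blood culture	blood culture
SYN:TE006	test	c reactive protein	c reactive protein|crp
SYN:OB001	observable	ejection fraction	ejection fraction
SYN:OB002	observable	pressure gradient	pressure gradient
SYN:OB003	observable	ascending aorta diameter	ascending aorta diameter
SYN:OB004	observable	body temperature	body temperature|temperature
SYN:BS001	body_structure	left ventricle	left ventricle
SYN:BS002	body_structure	right atrium	right atrium
SYN:BS003	body_structure	pulmonary artery	pulmonary artery
SYN:BS004	body_structure	mitral valve	mitral valve
SYN:QU001	qualifier	mild	mild
SYN:QU002	qualifier	moderate	moderate
SYN:QU003	qualifier	severe	severe
SYN:VA001	value	positive	positive
SYN:VA002	value	trace	trace
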