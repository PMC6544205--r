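code	description
A09	Diarrhoea and gastroenteritis of presumed infectious origin
C34	Malignant neoplasm of bronchus and lung
E10	Insulin-dependent diabetes mellitus
E11	Non-insulin-dependent diabetes mellitus
E119	Non-insulin-dependent diabetes mellitus without complications
F32	Depressive episode
G20	Parkinson disease
H59	Postprocedural disorders of eye and adnexa, not elsewhere classified
H60	Otitis externa
I00	Rheumatic fever without mention of heart involvement
I10	Essential (primary) hypertension
I20	Angina pectoris
I21	Acute myocardial infarction
I219	Acute myocardial infarction, unspecified
I22	Subsequent myocardial infarction
I23	Certain current complications following acute myocardial infarction
I24	Other acute ischaemic heart diseases
I25	Chronic ischaemic heart disease
I251	Atherosclerotic heart disease
I42	Cardiomyopathy
I43	Cardiomyopathy in diseases classified elsewhere
I60	Subarachnoid haemorrhage
I61	Intracerebral haemorrhage
I62	Other nontraumatic intracranial haemorrhage
I63	Cerebral infarction
I639	Cerebral infarction, unspecified
I64	Stroke, not specified as haemorrhage or infarction
I65	Occlusion and stenosis of precerebral arteries, not resulting in cerebral infarction
I66	Occlusion and stenosis of cerebral arteries, not resulting in cerebral infarction
I67	Other cerebrovascular diseases
I68	Cerebrovascular disorders in diseases classified elsewhere
I69	Sequelae of cerebrovascular disease
I74	Arterial embolism and thrombosis
I99	Other and unspecified disorders of circulatory system
J09	Influenza due to certain identified influenza viruses
J10	Influenza due to other identified influenza virus
J11	Influenza, virus not identified
J12	Viral pneumonia, not elsewhere classified
J13	Pneumonia due to Streptococcus pneumoniae
J14	Pneumonia due to Haemophilus influenzae
J15	Bacterial pneumonia, not elsewhere classified
J16	Pneumonia due to other infectious organisms, not elsewhere classified
J17	Pneumonia in diseases classified elsewhere
J18	Pneumonia, organism unspecified
J189	Pneumonia, unspecified
J20	Acute bronchitis
J21	Acute bronchiolitis
J22	Unspecified acute lower respiratory infection
J45	Asthma
K35	Acute appendicitis
M54	Dorsalgia
N39	Other disorders of urinary system
P23	Congenital pneumonia
R51	Headache
U04	Severe acute respiratory syndrome [SARS]
Z00	General examination and investigation of persons without complaint and reported diagnosis
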