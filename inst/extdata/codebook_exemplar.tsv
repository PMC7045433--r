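system	code	wildcard	category	min_age	max_age	sources	note
ICD10AM	F40	1	anxiety	0	24	NMDS;PRIMHD;SOCRATES	phobic anxiety disorders
ICD10AM	F41	1	anxiety	0	24	NMDS;PRIMHD;SOCRATES	other anxiety disorders
ICD10AM	F42	1	anxiety	0	24	NMDS;PRIMHD;SOCRATES	obsessive-compulsive disorder
ICD10AM	F32	1	depression	0	24	NMDS;PRIMHD;SOCRATES	depressive episode
ICD10AM	F33	1	depression	0	24	NMDS;PRIMHD;SOCRATES	recurrent depressive disorder
ICD10AM	F93	1	emotional	0	24	NMDS;PRIMHD	emotional disorders with onset specific to childhood
ICD10AM	F30	1	bipolar	0	24	NMDS;PRIMHD	manic episode
ICD10AM	F31	1	bipolar	0	24	NMDS;PRIMHD	bipolar affective disorder
ICD10AM	F1	1	substance	0	24	NMDS;PRIMHD;SOCRATES	mental and behavioural disorders due to psychoactive substance use
ICD10AM	F50	1	eating	0	24	NMDS;PRIMHD	eating disorders
ICD10AM	F90	1	disruptive	0	24	NMDS;PRIMHD;SOCRATES	hyperkinetic disorders
ICD10AM	F91	1	disruptive	0	24	NMDS;PRIMHD;SOCRATES	conduct disorders
ICD10AM	F2	1	psychosis	0	24	NMDS;PRIMHD;SOCRATES	schizophrenia, schizotypal and delusional disorders
ICD10AM	F60	1	personality	0	24	NMDS;PRIMHD;SOCRATES	specific personality disorders
ICD10AM	F61	1	personality	0	24	NMDS;PRIMHD;SOCRATES	mixed personality disorders
ICD10AM	F51	1	sleep	0	24	NMDS;PRIMHD	nonorganic sleep disorders
ICD10AM	G47	1	sleep	0	24	NMDS;PRIMHD	sleep disorders
ICD10AM	X6	1	self_harm	0	24	NMDS;MORTALITY	intentional self-harm X60-X69
ICD10AM	X7	1	self_harm	0	24	NMDS;MORTALITY	intentional self-harm X70-X79
ICD10AM	X80	1	self_harm	0	24	NMDS;MORTALITY	intentional self-harm
ICD10AM	X81	1	self_harm	0	24	NMDS;MORTALITY	intentional self-harm
ICD10AM	X82	1	self_harm	0	24	NMDS;MORTALITY	intentional self-harm
ICD10AM	X83	1	self_harm	0	24	NMDS;MORTALITY	intentional self-harm
ICD10AM	X84	1	self_harm	0	24	NMDS;MORTALITY	intentional self-harm
ICD10AM	F94	1	other_mh	0	24	NMDS;PRIMHD	disorders of social functioning, childhood onset
ICD10AM	F95	1	other_mh	0	24	NMDS;PRIMHD	tic disorders
ICD10AM	F98	1	other_mh	0	24	NMDS;PRIMHD	other childhood-onset behavioural and emotional disorders
ICD10AM	F99	1	mh_not_defined	0	24	NMDS;PRIMHD	mental disorder not otherwise specified
DSMIV	300.02	0	anxiety	0	24	PRIMHD;SOCRATES	generalised anxiety disorder
DSMIV	296.32	0	depression	0	24	PRIMHD;SOCRATES	major depressive disorder, recurrent, moderate
DSMIV	307.1	0	eating	0	24	PRIMHD	anorexia nervosa
DSMIV	312.8	0	disruptive	0	24	PRIMHD;SOCRATES	conduct disorder
ACTIVITY_TYPE	T16	0	substance	0	24	PRIMHD	alcohol and drug service activity
TEAM_TYPE	16	0	substance	0	24	PRIMHD	alcohol and drug specialist team
CHEMICAL_ID	fluoxetine	0	emotional	0	24	PHARMS	used for both anxiety and depression; category cannot be distinguished
CHEMICAL_ID	citalopram	0	emotional	0	24	PHARMS	used for both anxiety and depression
CHEMICAL_ID	amitriptyline	0	depression	20	24	PHARMS	depression rubric for ages 20 and over only; younger dispensing commonly neuropathic pain
CHEMICAL_ID	buspirone	0	anxiety	0	24	PHARMS	anxiolytic
CHEMICAL_ID	lithium_carbonate	0	bipolar	0	24	PHARMS	mood stabiliser
CHEMICAL_ID	methylphenidate	0	disruptive	0	24	PHARMS	ADHD stimulant
CHEMICAL_ID	atomoxetine	0	disruptive	0	24	PHARMS	ADHD non-stimulant
CHEMICAL_ID	clozapine	0	psychosis	0	24	PHARMS	treatment-resistant schizophrenia
CHEMICAL_ID	methadone	0	substance	10	24	PHARMS	opioid substitution treatment
CHEMICAL_ID	naltrexone	0	substance	10	24	PHARMS	alcohol/opioid dependence
CHEMICAL_ID	melatonin	0	sleep	0	24	PHARMS	sleep onset disorder
CHEMICAL_ID	zopiclone	0	sleep	15	24	PHARMS	hypnotic, adolescents and young adults
CHEMICAL_ID	risperidone	0	mh_not_defined	0	24	PHARMS	several plausible indications (psychosis, disruptive behaviour, OCD, bipolar, emotional dysregulation)
CHEMICAL_ID	quetiapine	0	mh_not_defined	0	24	PHARMS	several plausible indications
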