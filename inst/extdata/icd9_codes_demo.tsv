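code	description
0010	Cholera due to vibrio cholerae
1629	Malignant neoplasm of bronchus and lung unspecified
25000	Diabetes mellitus without mention of complication type ii or unspecified type
410	Acute myocardial infarction
4109	Acute myocardial infarction of unspecified site
411	Other acute and subacute forms of ischemic heart disease
412	Old myocardial infarction
413	Angina pectoris
414	Other forms of chronic ischemic heart disease
4254	Other primary cardiomyopathies
428	Heart failure
4280	Congestive heart failure unspecified
430	Subarachnoid hemorrhage
431	Intracerebral hemorrhage
434	Occlusion of cerebral arteries
436	Acute but ill-defined cerebrovascular disease
480	Viral pneumonia
486	Pneumonia organism unspecified
4919	Unspecified chronic bronchitis
7840	Headache
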