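chapter	block_start	block_end	description
1	001	139	Infectious and Parasitic Diseases
2	140	239	Neoplasms
3	240	279	Endocrine, Nutritional and Metabolic Diseases, and Immunity Disorders
4	280	289	Diseases of the Blood and Blood-forming Organs
5	290	319	Mental Disorders
6	320	389	Diseases of the Nervous System and Sense Organs
7	390	459	Diseases of the Circulatory System
8	460	519	Diseases of the Respiratory System
9	520	579	Diseases of the Digestive System
10	580	629	Diseases of the Genitourinary System
11	630	679	Complications of Pregnancy, Childbirth, and the Puerperium
12	680	709	Diseases of the Skin and Subcutaneous Tissue
13	710	739	Diseases of the Musculoskeletal System and Connective Tissue
14	740	759	Congenital Anomalies
15	760	779	Certain Conditions Originating in the Perinatal Period
16	780	799	Symptoms, Signs and Ill-defined Conditions
17	800	999	Injury and Poisoning
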