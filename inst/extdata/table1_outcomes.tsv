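outcome	source	dataset	n_cases	n_controls
Hodgkin lymphoma	FinnGen	CD2_HODGKIN_LYMPHOMA_EXALLC	846	324650
Diffuse large B-cell lymphoma	FinnGen	C3_DLBCL_EXALLC	1050	314193
Follicular lymphoma	FinnGen	CD2_FOLLICULAR_LYMPHOMA_EXALLC	1181	324650
Mantle cell lymphoma	FinnGen	C3_MANTLE_CELL_LYMPHOMA_EXALLC	210	314193
Marginal zone B-cell lymphoma	FinnGen	C3_MARGINAL_ZONE_LYMPHOMA_EXALLC	202	314193
Mature T/NK-cell lymphomas	FinnGen	CD2_TNK_LYMPHOMA_EXALLC	363	324650
Waldenstrom macroglobulinemia, lymphoplasmacytic lymphoma	FinnGen	C3_MACROGLOBULINEMIA_EXALLC	88	314193
Other and unspecified types of non Hodgkin lymphoma	FinnGen	CD2_NONHODGKIN_NAS_EXALLC	1171	324650
Non-Hodgkin lymphoma	FinnGen	C3_NONHODGKIN_EXALLC	1072	314193
Lymphoid leukaemia	FinnGen	CD2_LYMPHOID_LEUKAEMIA_EXALLC	1617	324650
Acute lymphocytic leukaemia	FinnGen	C3_ALL_EXALLC	197	314192
Chronic lymphocytic leukaemia	FinnGen	C3_CLL_EXALLC	668	314189
Myeloid leukaemia	FinnGen	CD2_MYELOID_LEUKAEMIA_EXALLC	734	324650
Acute myeloid leukaemia	FinnGen	C3_AML_EXALLC	244	314192
Chronic myeloid leukaemia	FinnGen	C3_CML_EXALLC	115	314192
Chronic myeloid leukaemia [CML] BCR/ABL+	FinnGen	CML	258	409880
Monocytic leukaemia	FinnGen	CD2_MONOCYTIC_LEUKAEMIA_EXALLC	85	324650
Leukaemia of unspecified cell type	FinnGen	CD2_LEUKAEMIA_NAS_EXALLC	239	324650
Other leukaemias of specified cell type	FinnGen	CD2_OTHER_LEUKAEMIA_SPECIFIED_EXALLC	67	324650
Multiple myeloma and malignant plasma cell neoplasms	FinnGen	CD2_MULTIPLE_MYELOMA_PLASMA_CELL_EXALLC	1337	324650
Multiple myeloma	FinnGen	C3_MULT_MYELOMA_EXALLC	623	314185
Myeloproliferative diseases (CML excluded)	FinnGen	MYELOPROF_NONCML	2043	409880
Chronic myeloproliferative disease	FinnGen	CHRONMYELOPRO	354	409880
Essential (haemorrhagic) thrombocythaemia	FinnGen	THROMBOCYTAEMIA	1062	313473
Polycythaemia vera	FinnGen	POLYCYTVERA	1004	313577
Eosinophilic disease (BM)	FinnGen	ESOSINOPHIL_DISEASE	441	230284
Malignant immunoproliferative diseases	FinnGen	CD2_IMMUNOPROLIFERATIVE_EXALLC	250	324650
Lymphomas	UK Biobank	UKB_LYMPHOMAS	1752	359442
Leukaemia	UK Biobank	UKB_LEUKAEMIA	1260	372016
Lymphoid leukaemia	UK Biobank	UKB_LYMPHOID_LEUKAEMIA	760	372016
Myeloid leukaemia	UK Biobank	UKB_MYELOID_LEUKAEMIA	462	372016
Multiple myeloma	UK Biobank	UKB_MULT_MYELOMA	601	372016
Myeloproliferative neoplasms	UK Biobank	UKB_MYELOPROLIFERATIVE	1086	407155
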