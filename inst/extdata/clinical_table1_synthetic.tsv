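patient_id	age	sex	smoking	drinking	stage	tumor_size	histology	treatment_after_surgery	egfr_classic	dfs_time	dfs_event	os_time	os_event
T001	23	Male	smoker	Drinking	I	1.6	P-SCLC	TRUE	TRUE	16.2	TRUE	33.27	TRUE
T002	45	Male	smoker	Drinking	I	5	P-SCLC	TRUE	TRUE	18.19	TRUE	33.99	TRUE
T003	48	Male	smoker	Drinking	I	8	P-SCLC	TRUE	FALSE	13.16	TRUE	13.16	TRUE
T004	50	Male	smoker	Drinking	I	10	P-SCLC	TRUE	FALSE	24.82	TRUE	30.57	TRUE
T005	52	Male	smoker	Drinking	I	12	P-SCLC	TRUE	FALSE	24.54	TRUE	24.54	TRUE
T006	54	Male	smoker	Drinking	I	14	P-SCLC	TRUE	FALSE	17.61	TRUE	20.61	TRUE
T007	55	Male	smoker	Drinking	I	15	P-SCLC	TRUE	FALSE	27.57	TRUE	27.57	TRUE
T008	56	Male	smoker	Drinking	I	16	P-SCLC	TRUE	FALSE	8.31	TRUE	8.31	TRUE
T009	57	Male	smoker	Drinking	I	17	P-SCLC	TRUE	FALSE	11.64	TRUE	25.02	TRUE
T010	58	Male	smoker	Drinking	I	18	P-SCLC	TRUE	FALSE	26.56	TRUE	26.56	TRUE
T011	60	Male	smoker	Drinking	I	19	P-SCLC	TRUE	FALSE	18.65	TRUE	18.65	TRUE
T012	61	Male	smoker	Drinking	I	20	P-SCLC	TRUE	FALSE	25.33	TRUE	27.01	TRUE
T013	62	Male	smoker	Drinking	II	21	P-SCLC	TRUE	FALSE	26.37	TRUE	33.91	TRUE
T014	63	Male	smoker	Drinking	II	21.5	P-SCLC	TRUE	FALSE	12.17	TRUE	12.17	TRUE
T015	63	Male	smoker	Drinking	II	22	P-SCLC	TRUE	FALSE	11.95	FALSE	11.95	FALSE
T016	64	Male	smoker	Drinking	II	22	P-SCLC	TRUE	FALSE	24.45	FALSE	47.44	FALSE
T017	64	Male	smoker	Drinking	II	22	P-SCLC	TRUE	FALSE	33.39	FALSE	43.86	FALSE
T018	64	Male	smoker	Drinking	III	23	P-SCLC	TRUE	FALSE	7.21	FALSE	18.56	FALSE
T019	64	Male	smoker	Drinking	III	24	P-SCLC	TRUE	FALSE	23.05	FALSE	23.05	FALSE
T020	65	Male	smoker	Drinking	III	25	P-SCLC	TRUE	FALSE	26.07	FALSE	35.72	FALSE
T021	65	Male	smoker	Never	III	26	P-SCLC	TRUE	FALSE	8.49	FALSE	43.78	FALSE
T022	66	Male	smoker	Never	III	28	P-SCLC	TRUE	FALSE	5.97	FALSE	59.14	FALSE
T023	66	Male	smoker	Never	III	30	P-SCLC	TRUE	FALSE	20.17	FALSE	47.98	FALSE
T024	67	Male	smoker	Never	III	32	P-SCLC	FALSE	FALSE	31.84	FALSE	38.32	FALSE
T025	67	Male	smoker	Never	III	35	P-SCLC	FALSE	FALSE	30.14	FALSE	52.48	FALSE
T026	68	Male	smoker	Never	III	38	P-SCLC	FALSE	FALSE	19.47	FALSE	19.47	FALSE
T027	68	Male	smoker	Never	III	40	P-SCLC	FALSE	FALSE	9.3	FALSE	23.56	FALSE
T028	69	Male	smoker	Never	III	45	P-SCLC	FALSE	FALSE	37.95	FALSE	51.41	FALSE
T029	70	Male	non-smoker	Never	III	50	P-SCLC	FALSE	FALSE	13.86	FALSE	44.66	FALSE
T030	71	Male	non-smoker	Never	III	60	P-SCLC	FALSE	FALSE	8.52	TRUE	22.03	FALSE
T031	72	Male	non-smoker	Never	III	80	P-SCLC	FALSE	FALSE	12.15	FALSE	12.15	FALSE
T032	73	Female	non-smoker	Never	III	120	P-SCLC	FALSE	FALSE	14.99	FALSE	17.02	FALSE
T033	74	Female	non-smoker	Never	III	200	P-SCLC	FALSE	FALSE	20.82	FALSE	20.82	FALSE
T034	75	Female	NA	NA	III	420	P-SCLC	FALSE	FALSE	17.59	FALSE	33.97	FALSE
T035	50	Male	smoker	Drinking	I	2.4	C-SCLC	TRUE	TRUE	4.13	TRUE	4.13	TRUE
T036	58	Male	smoker	Drinking	I	10	C-SCLC	TRUE	TRUE	31.71	FALSE	45.97	FALSE
T037	62	Male	smoker	Never	I	20	C-SCLC	TRUE	FALSE	9.95	TRUE	10.39	FALSE
T038	64	Male	non-smoker	Never	II	25.66	C-SCLC	FALSE	FALSE	4.08	FALSE	28.77	FALSE
T039	70	Female	non-smoker	Never	II	40	C-SCLC	FALSE	FALSE	8.02	FALSE	35.72	FALSE
T040	76	Female	non-smoker	Never	III	54	C-SCLC	FALSE	FALSE	10.08	FALSE	10.08	FALSE
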