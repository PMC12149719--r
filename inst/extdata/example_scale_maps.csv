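study_id,grade_label,band
synthetic_study_A,0,light
synthetic_study_A,1,light
synthetic_study_A,1.5,light
synthetic_study_A,2,moist_desquamation
synthetic_study_A,2.5,moist_desquamation
synthetic_study_A,3,severe
synthetic_study_B,dry desquamation,light
synthetic_study_B,erythema,light
synthetic_study_B,patchy moist desquamation,moist_desquamation
synthetic_study_B,confluent moist desquamation,moist_desquamation
synthetic_study_B,ulceration,severe
synthetic_study_B,necrosis,severe
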