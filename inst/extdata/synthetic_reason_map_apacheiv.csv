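source_code,category
401,nonop_asthma_allergy
402,nonop_copd
403,nonop_pulmonary_edema
404,nonop_post_respiratory_arrest
405,nonop_aspiration_poisoning_toxic
406,nonop_pulmonary_embolus
407,nonop_respiratory_infection
408,nonop_respiratory_neoplasm
409,nonop_hypertension
410,nonop_rhythm_disturbance
411,nonop_congestive_heart_failure
412,nonop_hemorrhagic_shock_hypovolemia
413,nonop_coronary_artery_disease
414,nonop_sepsis
415,nonop_post_cardiac_arrest
416,nonop_cardiogenic_shock
417,nonop_dissecting_aneurysm
418,nonop_multiple_trauma
419,nonop_head_trauma
420,nonop_seizure_disorder
421,nonop_intracranial_hemorrhage
422,nonop_drug_overdose
423,nonop_diabetic_ketoacidosis
424,nonop_gi_bleeding
425,nonop_metabolic_renal_other
426,nonop_respiratory_other
427,nonop_neurologic_other
428,nonop_cardiovascular_other
429,nonop_gastrointestinal_other
430,postop_multiple_trauma
431,postop_chronic_cardiovascular
432,postop_peripheral_vascular
433,postop_heart_valve
434,postop_craniotomy_neoplasm
435,postop_renal_neoplasm
436,postop_renal_transplant
437,postop_head_trauma
438,postop_thoracic_neoplasm
439,postop_craniotomy_ich
440,postop_laminectomy_spinal
441,postop_hemorrhagic_shock
442,postop_gi_bleeding
443,postop_gi_neoplasm
444,postop_respiratory_insufficiency
445,postop_gi_perforation
446,postop_metabolic_renal_other
447,postop_respiratory_other
448,postop_neurologic_other
449,postop_cardiovascular_other
450,postop_gastrointestinal_other
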