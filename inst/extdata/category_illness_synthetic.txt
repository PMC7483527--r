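# Synthetic demonstration word list: illness category.
ache
allergy
bedridden
clinic
cough
disease
dizzy
doctor
doctors
fever
flu
headache
hospital
ill
illness
infection
injured
injury
medicine
nausea
nurse
pain
pill
pills
sick
symptom
symptoms
virus
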