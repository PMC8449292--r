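admission_id,text
A001,"Patient admitted after overdose. Reports feeling hopeless and worthless; denies current suicidal ideation. Severe insomnia for two weeks, appears restless and agitated on the ward."
A002,"Admitted following a suicide attempt. Withdrawn and isolated on interview; social withdrawal noted by family. Mildly confused on admission, no memory impairment."
A003,"Patient expresses guilt about recent events and persistent anxious mood. Sleep disturbance with early waking. Motivated to engage in treatment; some optimism about discharge planning."
A004,"Brought in by family after suicide planning disclosed. Inattentive during exam with occasional perseveration. Argumentative with staff, later withdrawn. Lethargic during the day after poor sleep."
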