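domain,term
positive_valence,reward
positive_valence,motivated
positive_valence,pleasure
positive_valence,enjoyment
positive_valence,optimistic
negative_valence,hopeless
negative_valence,worthless
negative_valence,guilt
negative_valence,"suicidal ideation"
negative_valence,anxious
cognitive_systems,confused
cognitive_systems,disoriented
cognitive_systems,"memory impairment"
cognitive_systems,inattentive
cognitive_systems,perseveration
social_processes,withdrawn
social_processes,isolated
social_processes,"social withdrawal"
social_processes,argumentative
social_processes,dependent
arousal_regulatory,insomnia
arousal_regulatory,agitation
arousal_regulatory,restless
arousal_regulatory,"sleep disturbance"
arousal_regulatory,lethargic
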