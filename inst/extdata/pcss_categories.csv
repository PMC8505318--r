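item,category
headache,physical
nausea,physical
vomiting,physical
balance_problems,physical
dizziness,physical
visual_problems,physical
fatigue,physical
sensitivity_to_light,physical
sensitivity_to_noise,physical
numbness_tingling,physical
feeling_slowed_down,cognitive
feeling_in_a_fog,cognitive
difficulty_concentrating,cognitive
difficulty_remembering,cognitive
irritability,emotional
sadness,emotional
nervousness,emotional
more_emotional,emotional
drowsiness,sleep
sleeping_less,sleep
sleeping_more,sleep
trouble_falling_asleep,sleep
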