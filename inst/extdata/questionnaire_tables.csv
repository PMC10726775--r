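#table q1_suitability
,yes,no
sexless,21,2
female,22,3

#table q2_sexless
,yes,no
sexless,14,8
female,9,16

#table q3_features
,head,shoulders,arms,legs,buttocks,abdomen,waist,chest,feet
sexless,6,5,5,5,6,5,10,14,3
female,3,2,0,2,2,0,8,12,1

#table q4_importance
,important,unimportant,no_opinion
sexless,14,9,0
female,11,9,5

#table q5_disturbance
,bothers_me,does_not_bother_me,no_opinion
sexless,8,9,6
female,8,13,4
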