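correlate,domain,RTLS_Total,RTLS_Emotional,RTLS_Social,UCLA_20,UCLA_3,SI_Direct,SI_Indirect,SI_DirectFreq
Age,demography,0.05,-0.03,0.13,0.08,-0.05,-0.09,0,-0.1
Gender,demography,-0.1,-0.04,-0.15,-0.15,-0.03,-0.04,-0.1,-0.03
Education,demography,-0.12,-0.1,-0.11,-0.11,-0.06,-0.11,-0.1,-0.11
Partnered,demography,-0.19,-0.21,-0.13,-0.18,-0.1,-0.25,-0.24,-0.23
Neuroticism,personality,0.29,0.34,0.18,0.24,0.37,0.21,0.19,0.26
Extraversion,personality,-0.34,-0.3,-0.33,-0.46,-0.33,-0.19,-0.2,-0.2
Openness,personality,-0.15,-0.08,-0.2,-0.2,-0.11,-0.07,-0.07,-0.03
Agreeableness,personality,-0.23,-0.17,-0.27,-0.29,-0.16,-0.1,-0.13,-0.08
Conscientiousness,personality,-0.21,-0.18,-0.21,-0.22,-0.17,-0.18,-0.15,-0.16
Shyness,personality,0.34,0.33,0.28,0.39,0.39,0.25,0.24,0.27
Sociability,personality,-0.3,-0.19,-0.37,-0.42,-0.2,-0.06,-0.13,-0.06
SelfEsteem,personality,-0.53,-0.53,-0.42,-0.49,-0.53,-0.47,-0.46,-0.5
AffiliationMotive,personality,-0.25,-0.11,-0.36,-0.4,-0.09,-0.04,-0.11,0
UnsatisfiedNeeds,personality,0.57,0.49,0.48,0.57,0.55,0.38,0.33,0.37
FrustratedAffiliation,personality,-0.06,-0.01,-0.1,-0.1,-0.01,-0.06,-0.07,0
Depressiveness,personality,0.62,0.61,0.52,0.64,0.58,0.49,0.48,0.56
SocialDesirability,personality,-0.05,-0.05,-0.05,-0.04,-0.05,-0.03,-0.01,-0.02
SatLife,satisfaction,-0.53,-0.51,-0.45,-0.53,-0.43,-0.49,-0.53,-0.49
SatEducation,satisfaction,-0.36,-0.34,-0.32,-0.36,-0.33,-0.32,-0.3,-0.33
SatLeisure,satisfaction,-0.45,-0.41,-0.4,-0.48,-0.38,-0.38,-0.4,-0.35
SatFriends,satisfaction,-0.66,-0.64,-0.55,-0.64,-0.6,-0.47,-0.47,-0.43
SatFamily,satisfaction,-0.42,-0.37,-0.41,-0.44,-0.37,-0.39,-0.35,-0.35
SatPartner,satisfaction,-0.34,-0.36,-0.26,-0.32,-0.21,-0.33,-0.34,-0.3
FriendsOverall,network,-0.32,-0.25,-0.35,-0.36,-0.24,-0.16,-0.17,-0.16
FriendsFacebook,network,-0.04,-0.01,-0.07,-0.08,-0.03,-0.05,-0.05,-0.03
FriendsHelp,network,-0.38,-0.29,-0.42,-0.37,-0.23,-0.19,-0.2,-0.17
FriendsInstrumental,network,-0.37,-0.31,-0.36,-0.35,-0.27,-0.22,-0.26,-0.21
FriendsAdvice,network,-0.22,-0.18,-0.23,-0.24,-0.16,-0.17,-0.19,-0.19
ContactFrequency,network,-0.22,-0.15,-0.27,-0.27,-0.13,-0.02,-0.08,-0.02
JointActivities,network,-0.41,-0.34,-0.42,-0.45,-0.31,-0.17,-0.15,-0.12
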