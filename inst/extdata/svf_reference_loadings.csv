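id,chaotic,socioeconomic,psychosocial
material_hardship,0.34,0.37,0.27
low_status_occupation,0.19,0.70,-0.17
unemployment,0.14,0.77,-0.11
long_term_unemployment,0.20,0.68,0.11
homelessness,0.04,0.38,0.43
marginal_homelessness,0.04,0.24,0.62
overcrowding,0.26,0.17,-0.30
transience,0.41,0.45,0.30
chronic_illness_parents,0.26,0.01,0.43
chronic_illness_siblings,0.05,0.27,0.12
mental_ill_health,0.37,0.08,0.40
alcohol_misuse,0.60,0.33,0.05
substance_abuse,0.72,0.20,0.24
sibling_death,0.23,-0.06,-0.01
stillbirth,0.15,-0.22,0.07
miscarriages_terminations,0.21,-0.16,0.36
limited_access_care,0.21,0.40,0.00
criminal_offending,0.73,0.15,0.13
long_term_criminal_offending,0.61,0.16,0.15
victim_of_crime,0.37,0.35,-0.09
domestic_violence,0.61,0.20,-0.20
domestic_violence_previous,0.14,0.40,0.43
child_abuse_neglect,0.63,0.37,0.17
risky_behaviours,0.05,0.20,0.57
lack_of_transport,0.01,0.53,0.35
geographic_isolation,0.07,0.14,-0.29
limited_social_support,0.28,0.38,0.35
multiple_partners,0.48,0.15,0.33
children_not_in_care,0.41,0.34,0.39
stressful_life_events,0.45,0.30,0.32
parental_history_abuse,0.20,0.37,0.19
parental_history_juvenile_offending,0.12,0.27,0.07
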