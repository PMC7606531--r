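id,name,dimension,method,in_queensland_svf
material_hardship,Limited material resources and financial hardship,income_material,BINARY_2,TRUE
low_status_occupation,Low status parental occupations,employment,CONTINUOUS_OCCUPATION,TRUE
unemployment,Unemployment,employment,BINARY_1,TRUE
long_term_unemployment,Long-term unemployment,employment,BINARY_1,TRUE
homelessness,Homelessness,housing,BINARY_2,TRUE
marginal_homelessness,Marginal homelessness,housing,BINARY_2,TRUE
overcrowding,Overcrowding,housing,BINARY_2,TRUE
transience,Transience and mobility,housing,LONGITUDINAL,TRUE
chronic_illness_parents,Chronic illness or disability in parents,health,PARENT_WEIGHTED,TRUE
chronic_illness_siblings,Chronic illness or disability in siblings,health,SIBLING_WEIGHTED,TRUE
mental_ill_health,Mental ill-health in parents,health,PARENT_WEIGHTED,TRUE
alcohol_misuse,Alcohol misuse,health,PARENT_WEIGHTED,TRUE
substance_abuse,Substance abuse,health,PARENT_WEIGHTED,TRUE
sibling_death,Previous liveborn sibling death,health,BINARY_2,TRUE
stillbirth,Previous stillbirth,health,EVENT_PREVALENCE,TRUE
miscarriages_terminations,Multiple miscarriages or terminations,health,EVENT_PREVALENCE,TRUE
limited_access_care,Limited access to primary care,health,EVENT_PREVALENCE,TRUE
criminal_offending,Criminal offending,crime_safety,PARENT_WEIGHTED,TRUE
long_term_criminal_offending,Long-term criminal offending,crime_safety,PARENT_WEIGHTED_LONGITUDINAL,TRUE
victim_of_crime,Victim of crime,crime_safety,PARENT_WEIGHTED,TRUE
domestic_violence,Domestic violence,crime_safety,LONGITUDINAL,TRUE
domestic_violence_previous,Domestic violence in previous relationships,crime_safety,BINARY_1,TRUE
child_abuse_neglect,Child abuse and neglect,crime_safety,BINARY_2,TRUE
risky_behaviours,Engagement in risky behaviours (sex work),crime_safety,LONGITUDINAL,TRUE
lack_of_transport,Lack of transport,transport_access,BINARY_1,TRUE
geographic_isolation,Geographic isolation,transport_access,REMOTENESS_WEIGHTED,TRUE
limited_social_support,Limited social support,family_social,BINARY_1,TRUE
multiple_partners,Multiple partners,family_social,PARENT_WEIGHTED,TRUE
children_not_in_care,Children not in care of biological parents,family_social,LONGITUDINAL,TRUE
stressful_life_events,Stressful life events,family_social,EVENT_PREVALENCE,TRUE
parental_history_abuse,Parental history of child abuse and neglect,intergenerational,PARENT_WEIGHTED,TRUE
parental_history_juvenile_offending,Parental history of juvenile offending,intergenerational,PARENT_WEIGHTED,TRUE
income_below_poverty,Family income below poverty line,income_material,NA,FALSE
healthcare_card,Government healthcare or concession card,income_material,NA,FALSE
early_school_leaver,Early school leaver,education_skills,NA,FALSE
very_early_school_leaver,Very early school leaver,education_skills,NA,FALSE
no_post_school_education,No advanced or vocational education,education_skills,NA,FALSE
poor_basic_skills,Poor basic skills,education_skills,NA,FALSE
public_housing,Public housing,housing,NA,FALSE
no_car_household,No access to car in household,transport_access,NA,FALSE
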