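id,group,target,average,label
improved_water,head_of_household,0.95,0.973,Household uses an improved water source
continuous_water,head_of_household,0.80,0.570,Water continuously available from habitual source for the last 2 weeks
ibrik,head_of_household,0.60,0.452,Household owns an Ibrik (water storage container used for washing)
soap,head_of_household,0.75,0.511,Household has at least one piece of soap (observed)
handwash_area,head_of_household,0.60,0.272,Hand-washing area within the living area
health_promoter,head_of_household,0.95,0.935,Household visited by a health promoter within the last 2 weeks
four_moments,head_of_household,0.75,0.370,Head of household knows four critical moments for hand washing with soap
handwash_adjacent,head_of_household,0.60,0.279,Hand-washing area with soap and water adjacent to habitual sanitation facility
improved_sanitation,head_of_household,NA,0.968,Household usually uses an improved sanitation facility
no_open_defecation,head_of_household,NA,0.968,Household does not practice open defecation
diarrhoea,caregiver,NA,NA,Child 0-59 months had diarrhoea in the last 2 weeks
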