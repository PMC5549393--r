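sa_id,n,improved_water,continuous_water,ibrik,soap,handwash_area,health_promoter,four_moments,handwash_adjacent,improved_sanitation,no_open_defecation,diarrhoea
SA1,19,19,16,16,18,18,19,18,9,19,19,4
SA2,19,19,9,4,9,5,18,7,9,18,18,5
SA3,19,19,8,3,2,0,19,1,1,18,18,7
SA4,19,16,9,10,13,0,19,11,1,19,19,6
SA5,19,19,14,10,8,1,15,0,3,19,19,7
SA6,19,19,8,8,6,5,16,2,8,17,17,3
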