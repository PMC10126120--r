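descriptor,level,count_nonTBI,count_TBI,denom_nonTBI,denom_TBI
Gender,Male,77,52,,
Gender,Female,0,1,,
Nicotine use,Yes,35,24,,
Nicotine use,No,42,29,,
Wound type,Transfemoral amputation,9,14,,
Wound type,Transtibial amputation,19,15,,
Wound type,Transhumeral amputation,0,1,,
Wound type,Transradial amputation,0,1,,
Wound type,Foot amputation,1,0,,
Wound type,Open fracture,30,12,,
Wound type,Closed fracture,1,0,,
Wound type,Knee disarticulation,1,3,,
Wound type,Shoulder disarticulation,0,1,,
Wound type,Soft tissue injury,16,6,,
Number of wounds,Single,26,4,,
Number of wounds,Multiple,51,49,,
Wound appearance,Gross purulence and necrotic tissue,13,12,240,154
Wound appearance,Some necrotic tissue but no purulence,93,52,240,154
Wound appearance,Some purulence but no necrotic tissue,4,4,240,154
Wound appearance,No purulence or necrotic tissue,130,85,240,154
HO wound,No,42,22,,
HO wound,Yes,35,30,,
HO wound,Unknown,0,1,,
Final outcome,Healed,67,43,,
Final outcome,Failed,10,10,,
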