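wound_id,patient_id,skin_type,surf1,epi1,dermal1,vasc1,surf2,epi2,dermal2,vasc2,clinical_judgment,outcome,days_to_graft
w01,p01,glabrous,0,1,1,0,0,1,1,0,superficial,healed_spontaneously,
w02,p02,hair_bearing,1,0,1,1,1,0,1,1,superficial,healed_spontaneously,
w03,p03,glabrous,1,1,1,0,1,1,0,0,superficial,healed_spontaneously,
w04,p04,hair_bearing,1,1,1,1,1,1,1,1,superficial,healed_spontaneously,
w05,p05,glabrous,0,1,2,1,0,1,2,1,deep,healed_spontaneously,
w06,p05,glabrous,1,0,2,1,1,0,2,1,superficial,healed_spontaneously,
w07,p06,hair_bearing,1,1,0,2,1,1,1,2,superficial,healed_spontaneously,
w08,p07,hair_bearing,1,1,2,1,1,1,2,2,deep,grafted,9
w09,p08,glabrous,1,0,2,2,1,0,2,2,deep,healed_spontaneously,
w10,p09,hair_bearing,1,1,2,2,1,1,2,2,deep,grafted,12
w11,p10,glabrous,1,0,1,1,1,1,1,1,superficial,healed_spontaneously,
w12,p11,hair_bearing,0,1,2,1,0,1,2,1,superficial,healed_spontaneously,
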