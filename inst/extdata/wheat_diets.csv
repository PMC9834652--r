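diet_id,ingredient_id,inclusion_pct_asfed,is_mixture_component,is_test_ingredient
BASAL,corn,71.61,TRUE,FALSE
BASAL,soybean_meal,24.95,TRUE,FALSE
BASAL,dicalcium_phosphate,0.90,FALSE,FALSE
BASAL,limestone,0.90,FALSE,FALSE
BASAL,salt,0.35,FALSE,FALSE
BASAL,premix,0.50,FALSE,FALSE
BASAL,l_lys_hcl,0.50,TRUE,FALSE
BASAL,dl_met,0.07,TRUE,FALSE
BASAL,l_thr,0.16,TRUE,FALSE
BASAL,l_val,0.06,TRUE,FALSE
WB1,corn,49.54,TRUE,FALSE
WB1,soybean_meal,17.26,TRUE,FALSE
WB1,dicalcium_phosphate,0.90,FALSE,FALSE
WB1,limestone,0.90,FALSE,FALSE
WB1,salt,0.35,FALSE,FALSE
WB1,premix,0.50,FALSE,FALSE
WB1,l_lys_hcl,0.35,TRUE,FALSE
WB1,dl_met,0.05,TRUE,FALSE
WB1,l_thr,0.11,TRUE,FALSE
WB1,l_val,0.04,TRUE,FALSE
WB1,wheat_bran_1,30.00,FALSE,TRUE
WB2,corn,49.54,TRUE,FALSE
WB2,soybean_meal,17.26,TRUE,FALSE
WB2,dicalcium_phosphate,0.90,FALSE,FALSE
WB2,limestone,0.90,FALSE,FALSE
WB2,salt,0.35,FALSE,FALSE
WB2,premix,0.50,FALSE,FALSE
WB2,l_lys_hcl,0.35,TRUE,FALSE
WB2,dl_met,0.05,TRUE,FALSE
WB2,l_thr,0.11,TRUE,FALSE
WB2,l_val,0.04,TRUE,FALSE
WB2,wheat_bran_2,30.00,FALSE,TRUE
WB3,corn,49.54,TRUE,FALSE
WB3,soybean_meal,17.26,TRUE,FALSE
WB3,dicalcium_phosphate,0.90,FALSE,FALSE
WB3,limestone,0.90,FALSE,FALSE
WB3,salt,0.35,FALSE,FALSE
WB3,premix,0.50,FALSE,FALSE
WB3,l_lys_hcl,0.35,TRUE,FALSE
WB3,dl_met,0.05,TRUE,FALSE
WB3,l_thr,0.11,TRUE,FALSE
WB3,l_val,0.04,TRUE,FALSE
WB3,wheat_bran_3,30.00,FALSE,TRUE
WB4,corn,49.54,TRUE,FALSE
WB4,soybean_meal,17.26,TRUE,FALSE
WB4,dicalcium_phosphate,0.90,FALSE,FALSE
WB4,limestone,0.90,FALSE,FALSE
WB4,salt,0.35,FALSE,FALSE
WB4,premix,0.50,FALSE,FALSE
WB4,l_lys_hcl,0.35,TRUE,FALSE
WB4,dl_met,0.05,TRUE,FALSE
WB4,l_thr,0.11,TRUE,FALSE
WB4,l_val,0.04,TRUE,FALSE
WB4,wheat_bran_4,30.00,FALSE,TRUE
WB5,corn,49.54,TRUE,FALSE
WB5,soybean_meal,17.26,TRUE,FALSE
WB5,dicalcium_phosphate,0.90,FALSE,FALSE
WB5,limestone,0.90,FALSE,FALSE
WB5,salt,0.35,FALSE,FALSE
WB5,premix,0.50,FALSE,FALSE
WB5,l_lys_hcl,0.35,TRUE,FALSE
WB5,dl_met,0.05,TRUE,FALSE
WB5,l_thr,0.11,TRUE,FALSE
WB5,l_val,0.04,TRUE,FALSE
WB5,wheat_bran_5,30.00,FALSE,TRUE
WB6,corn,49.54,TRUE,FALSE
WB6,soybean_meal,17.26,TRUE,FALSE
WB6,dicalcium_phosphate,0.90,FALSE,FALSE
WB6,limestone,0.90,FALSE,FALSE
WB6,salt,0.35,FALSE,FALSE
WB6,premix,0.50,FALSE,FALSE
WB6,l_lys_hcl,0.35,TRUE,FALSE
WB6,dl_met,0.05,TRUE,FALSE
WB6,l_thr,0.11,TRUE,FALSE
WB6,l_val,0.04,TRUE,FALSE
WB6,wheat_bran_6,30.00,FALSE,TRUE
WS,corn,49.54,TRUE,FALSE
WS,soybean_meal,17.26,TRUE,FALSE
WS,dicalcium_phosphate,0.90,FALSE,FALSE
WS,limestone,0.90,FALSE,FALSE
WS,salt,0.35,FALSE,FALSE
WS,premix,0.50,FALSE,FALSE
WS,l_lys_hcl,0.35,TRUE,FALSE
WS,dl_met,0.05,TRUE,FALSE
WS,l_thr,0.11,TRUE,FALSE
WS,l_val,0.04,TRUE,FALSE
WS,wheat_shorts,30.00,FALSE,TRUE
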