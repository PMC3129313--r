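item,value
vial_mass_g_20,NA
vial_mass_g_10,3.522
vial_mass_g_5,2.517
vial_mass_g_2,NA
vial_mass_g_1,1.713
reconstitution_syringe_mass_g,6.625
injection_syringe_mass_g,6.625
injection_syringe_cost,0.070
reconstitution_syringe_cost,0.060
waste_disposal_cost_per_kg,6.850
waste_disposal_cost_per_g,0.0069
safety_box_cost_per_dose,NA
discount_rate,0.03
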