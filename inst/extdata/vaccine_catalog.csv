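antigen,schedule,doses_per_person,doses_per_vial,packed_vol_per_dose,diluent_vol_per_dose,route,storage_class,formulation,open_vial_days,price_per_dose,shelf_life_days,active
BCG,birth,1,20,1.2,0.7,intradermal,refrigerator,lyophilized,NA,NA,730,TRUE
DTP-HepB-Hib,"6w,10w,14w",3,1,16.8,0,intramuscular,refrigerator,liquid,28,NA,730,TRUE
YF,9m,1,10,2.5,6.0,subcutaneous,refrigerator,lyophilized,NA,NA,730,TRUE
OPV,"birth,6w,10w,14w",4,20,1.0,0,oral,freezer,liquid,28,NA,730,TRUE
TT,"contact1,contact2,contact3,contact4,contact5",5,10,3.0,0,intramuscular,refrigerator,liquid,28,NA,730,TRUE
M,9m,1,10,2.6,0.5,subcutaneous,refrigerator,lyophilized,NA,0.246,730,TRUE
M,9m,1,5,5.2,0.5,subcutaneous,refrigerator,lyophilized,NA,0.450,730,FALSE
M,9m,1,2,13.1,0.5,subcutaneous,refrigerator,lyophilized,NA,NA,730,FALSE
M,9m,1,1,26.1,0.5,subcutaneous,refrigerator,lyophilized,NA,0.943,730,FALSE
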