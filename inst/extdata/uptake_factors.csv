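region,uptake_male,uptake_female,emphasis_anterior,emphasis_posterior,lesion_fwhm_px,primary_view
skull,1.10,1.35,1.00,1.00,9,anterior
cervical_spine,0.95,0.95,0.70,1.20,6,posterior
thoracic_spine,1.10,1.10,0.60,1.30,7,posterior
lumbar_spine,1.30,1.30,0.70,1.30,9,posterior
sternum,0.90,0.90,1.30,0.25,6,anterior
clavicle_left,0.65,0.65,1.20,0.50,5,anterior
clavicle_right,0.65,0.65,1.20,0.50,5,anterior
scapula_left,0.75,0.75,0.50,1.25,8,posterior
scapula_right,0.75,0.75,0.50,1.25,8,posterior
ribs_left,0.55,0.50,0.90,1.00,5,average
ribs_right,0.55,0.50,0.90,1.00,5,average
humerus_left,0.55,0.55,1.00,0.90,6,average
humerus_right,0.55,0.55,1.00,0.90,6,average
pelvis,1.15,1.15,1.10,0.95,14,average
femur_left,0.70,0.70,1.00,0.95,8,average
femur_right,0.70,0.70,1.00,0.95,8,average
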