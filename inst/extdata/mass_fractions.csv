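region,mass_fraction
skull,0.120
cervical_spine,0.030
thoracic_spine,0.100
lumbar_spine,0.080
sternum,0.020
clavicle_left,0.010
clavicle_right,0.010
scapula_left,0.025
scapula_right,0.025
ribs_left,0.040
ribs_right,0.040
humerus_left,0.030
humerus_right,0.030
pelvis,0.110
femur_left,0.075
femur_right,0.075
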