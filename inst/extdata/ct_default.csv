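material,hu,ed,mass_density
Air,-1000,0.001,0.001
Lung inhale,-800,0.190,0.200
Lung exhale,-500,0.511,0.500
Adipose,-96,0.930,0.945
Water,0,1.000,1.000
Muscle,43,1.043,1.060
Inner bone,230,1.140,1.200
Cortical bone,1300,1.700,1.822
Dense bone,3000,2.640,2.900
Max,6000,3.920,9.500
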