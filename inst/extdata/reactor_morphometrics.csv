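sample_id,glucan_release,xylan,lignin,degree_of_polymerization,particle_size,aspect_ratio,cell_wall_thickness,surface_roughness,delamination_porosity
Untreated,24.0,22.0,12.3,2000,0.15,1.78,1.29,7.60,3.41
ZC,68.7,8.8,24.2,1750,0.08,1.90,3.49,10.37,5.62
SG,88.0,4.8,25.0,1650,0.08,1.67,2.60,17.53,20.01
HS,95.2,3.2,24.8,1850,0.07,1.49,2.30,17.61,26.57
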