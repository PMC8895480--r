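material,direction,breakpoint_strain,slope,units
skin,tangential,0,0.1,MPa
skin,tangential,0.4,18.8,MPa
skin,normal,0,0.05,MPa
skin,normal,0.3,2.5,MPa
subcutaneous,normal,0,0.03,MPa
subcutaneous,normal,0.35,1.5,MPa
padding_foam,normal,0,0.06,MPa
padding_foam,normal,0.5,1.2,MPa
padding_foam,tangential,0,0.04,MPa
padding_foam,tangential,0.5,0.8,MPa
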