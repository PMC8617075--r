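name,T0_C,S0_psu,u0_m_s,vent_diameter_m,depth_m,rho_site,rho_ref,dz_ref,HS-,H2,CH4,Fe++,Mn++,HCO3-,NH4+,acetate,H+
TAG_like_synthetic,363,35.5,1.0,0.15,3650,1027.770,1027.754,500,3.5,0.15,0.124,5.0,0.68,3.4,0.01,0.3,0.3
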