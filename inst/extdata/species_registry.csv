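name,phase,charge,C,H,O,N,S,Fe,Mn,dGf0,dHf0
O2,aqueous,0,0,0,2,0,0,0,0,16.54,-12.09
H+,aqueous,1,0,1,0,0,0,0,0,0,0
H2O,liquid,0,0,2,1,0,0,0,0,-237.18,-285.83
HS-,aqueous,-1,0,1,0,0,1,0,0,12.05,-17.6
S0,solid,0,0,0,0,0,1,0,0,0,0
S2O3--,aqueous,-2,0,0,3,0,2,0,0,-522.5,-648.5
SO4--,aqueous,-2,0,0,4,0,1,0,0,-744.0,-909.6
CH4,aqueous,0,1,4,0,0,0,0,0,-34.35,-87.81
H2,aqueous,0,0,2,0,0,0,0,0,17.72,-4.04
CO2,aqueous,0,1,0,2,0,0,0,0,-385.98,-413.79
HCO3-,aqueous,-1,1,1,3,0,0,0,0,-586.94,-689.93
NH4+,aqueous,1,0,4,0,1,0,0,0,-79.45,-133.26
NO2-,aqueous,-1,0,0,2,1,0,0,0,-32.2,-104.6
NO3-,aqueous,-1,0,0,3,1,0,0,0,-110.91,-206.85
N2,aqueous,0,0,0,0,2,0,0,0,18.18,-10.44
Fe++,aqueous,2,0,0,0,0,0,1,0,-91.5,-92.25
Fe+++,aqueous,3,0,0,0,0,0,1,0,-17.24,-49.58
FeOOH,solid,0,0,1,2,0,0,1,0,-488.55,-559.33
Mn++,aqueous,2,0,0,0,0,0,0,1,-228.1,-220.75
MnO2,solid,0,0,0,2,0,0,0,1,-465.1,-520.0
acetate,aqueous,-1,2,3,2,0,0,0,0,-369.31,-486.01
DOC_r,aqueous,0,1,1.33333333333333,0.5,0,0,0,0,NA,NA
POC,solid,0,1,1.33333333333333,0.5,0,0,0,0,NA,NA
biomass,biomass,0,1,1.8,0.5,0.2,0,0,0,-67.0,-91.0
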