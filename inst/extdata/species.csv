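# ionbudget-schema: species/1
name,formula,molar_mass,charge,element,element_stoichiometry,element_molar_mass
H,H+,1.008,1,H,1,1.008
NH4,NH4+,18.039,1,N,1,14.007
NO3,NO3-,62.004,-1,N,1,14.007
SO4,SO4^2-,96.06,-2,S,1,32.06
Cl,Cl-,35.45,-1,Cl,1,35.45
Ca,Ca^2+,40.078,2,Ca,1,40.078
Mg,Mg^2+,24.305,2,Mg,1,24.305
K,K+,39.098,1,K,1,39.098
Na,Na+,22.99,1,Na,1,22.99
Al,Al^3+,26.982,3,Al,1,26.982
Mn,Mn^2+,54.938,2,Mn,1,54.938
Fe,Fe^3+,55.845,3,Fe,1,55.845
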