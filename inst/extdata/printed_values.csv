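quantity,group,d_nm,value,sd,unit
chi,CB_no_soluble_SDF1a,11,97.0,6.7,percent
chi,CB_no_soluble_SDF1a,18,94.0,14.1,percent
chi,CB_soluble_SDF1a,11,93.1,6.7,percent
chi,CB_soluble_SDF1a,18,52.0,24.4,percent
area,CB_no_soluble_SDF1a,11,16.0,8.0,um2
area,CB_no_soluble_SDF1a,18,6.5,2.0,um2
area,CB_soluble_SDF1a,11,9.5,6.4,um2
area,CB_soluble_SDF1a,18,2.0,1.9,um2
pstar,CB_no_soluble_SDF1a,11,7.0,2.5,MPa
pstar,CB_no_soluble_SDF1a,18,3.2,0.2,MPa
pstar,CB_soluble_SDF1a,11,3.6,0.7,MPa
pstar,CB_soluble_SDF1a,18,2.2,0.4,MPa
pstar,SDF1a_CB,11,6.4,NA,MPa
pstar,Ncadherin_CB,11,2.8,NA,MPa
pstar,PB_HSC,11,5.8,NA,MPa
chi,PB_HSC,11,55,NA,percent
chi,CB_HSC,11,97,NA,percent
chi,LB_AML,11,88,NA,percent
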