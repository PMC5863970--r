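target,ligand_id,n,lowest_energy_kcal,mean_energy_kcal,mean_ki_nm,se_ki_nm,ci_low_nm,ci_high_nm,pki,constant,note
CRAF,BBR,50,-7.88,-7.80,1680,47,1588,1772,5.77,Ki,
CRAF,BBR-6,50,-8.60,-8.22,1019,57,907,1131,5.99,Ki,
CRAF,BBR-7,50,-9.68,-8.05,1914,48,1820,2008,5.72,Ki,
CRAF,BBR-9,50,-9.60,-9.12,265,50,167,363,6.58,Ki,
CRAF,BBR-10,50,-9.20,-8.70,374,43,290,458,6.46,Ki,printed pKi inconsistent with the row's own printed mean Ki (-log10 of 374 nM is 6.43)
CRAF,Vemurafenib,50,-11.12,-8.66,975,218,548,1402,6.02,Ki,
CRAF,ATP-Mg,50,-11.06,-10.73,26,14,1,53,8.59,Kd,dissociation constant; printed pKd is 1.0 unit above -log10(Kd in M); printed lower bound 1 where mean - 1.96*SE = -1.4
BRAF,BBR,50,-9.55,-8.52,832,326,193,1471,6.08,Ki,
BRAF,BBR-2,50,-10.38,-9.01,332,81,173,491,6.48,Ki,
BRAF,BBR-6,50,-10.89,-9.06,378,163,59,698,6.42,Ki,
BRAF,BBR-7,50,-11.62,-9.75,245,110,29,461,6.60,Ki,
BRAF,BBR-9,50,-10.64,-9.76,155,29,98,212,6.81,Ki,
BRAF,BBR-10,50,-11.01,-9.27,269,105,63,332,6.57,Ki,printed upper bound asymmetric with its own lower bound (269-63=206 vs 332-269=63); mean + 1.96*SE = 475; lower bound consistent
BRAF,Sorafenib,20,-9.36,-8.66,611,36,540,682,6.21,Ki,
BRAF,Vemurafenib,50,-11.88,-9.11,550,118,432,668,6.26,Ki,printed interval equals mean +/- 1*SE rather than mean +/- 1.96*SE
BRAF,ATP-Mg,50,-12.56,-11.50,8.00,3.7,0.8,15.2,9.10,Kd,dissociation constant; printed pKd is 1.0 unit above -log10(Kd in M)
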