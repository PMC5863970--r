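id,pubchem_cid,mw_da,n_hba,n_hbd,n_tdof,formal_charge,n_rot,n_rb,logp,tpsa_a2,n_polar,nha
BBR,2353,336.36,4,0,2,1,2,27,2.473,39.93,5,25
BBR-2,3005463,406.17,5,0,6,1,6,28,3.734,57.87,6,30
BBR-3,49865302,392.15,5,0,5,1,5,28,3.165,57.87,6,29
BBR-4,72704,322.11,4,1,2,1,1,27,2.152,50.93,5,24
BBR-5,3084288,322.11,4,1,2,1,1,27,2.152,50.93,5,24
BBR-6,15061301,364.12,5,0,3,1,3,28,2.343,57.87,6,27
BBR-7,NA,481.15,4,0,5,1,5,35,3.65,40.16,5,35
BBR-8,10790783,350.14,4,0,3,1,3,27,2.896,39.93,5,26
BBR-9,NA,479.13,4,0,5,1,5,35,4.5,40.16,5,35
BBR-10,NA,495.17,4,0,5,1,5,36,4.73,40.16,5,36
Vemurafenib,42611257,489.07,6,2,7,0,7,29,2.786,96.01,6,33
Sorafenib,216239,464.09,7,3,6,0,9,25,1.568,91.82,7,32
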