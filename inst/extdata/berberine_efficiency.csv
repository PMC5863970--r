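ligand_id,n_polar,nha,mw_kd,logp,tpsa_a2,pki_printed,nsei,nbei,nbei_log,mbei,lle,note
BBR,5,25,0.3364,2.473,39.93,5.90,1.22,0.24,7.48,5.62,3.61,
BBR-2,6,30,0.4062,3.734,57.87,4.85,1.08,0.22,7.96,6.08,2.75,
BBR-3,6,29,0.3922,3.165,57.87,5.35,0.98,0.20,7.36,5.47,2.74,printed mBEI violates the table's own identity mBEI - nBEI = log10(MW/nha) by 0.021
BBR-4,5,24,0.3221,2.152,50.93,5.68,1.16,0.24,7.19,5.31,3.66,
BBR-5,5,24,0.3221,2.152,50.93,5.78,1.22,0.26,7.49,5.61,3.96,
BBR-6,6,27,0.3641,2.343,57.87,5.69,1.07,0.24,7.85,5.98,4.71,printed LLE inconsistent with pKi - LogP under every printed pKi (campaign pKi gives 4.08)
BBR-7,5,35,0.4812,3.65,40.16,4.53,1.32,0.19,8.15,6.28,2.96,
BBR-8,5,26,0.3501,2.896,39.93,5.39,1.24,0.24,7.62,5.74,3.31,
BBR-9,5,35,0.4791,4.5,40.16,4.87,1.36,0.20,8.35,6.48,2.31,
BBR-10,5,36,0.4952,4.73,40.16,4.98,1.31,0.18,8.13,6.25,1.84,
Vemurafenib,6,33,0.4891,2.786,96.01,6.26,1.04,0.19,7.78,5.92,3.47,printed mBEI violates the table's own identity mBEI - nBEI = log10(MW/nha) by 0.031
Sorafenib,7,32,0.4641,1.568,91.82,6.21,0.89,0.19,7.72,5.90,4.64,
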