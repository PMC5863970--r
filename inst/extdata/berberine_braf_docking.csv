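ligand_id,crystal_id,n_clusters,torsional_kcal,lowest_energy_kcal,mean_energy_kcal,lowest_ki_nm,mean_ki_nm,pki,note
BBR,1uwh,2,0.60,-8.41,-8.33,684.74,832,6.08,
BBR,1uwj,1,0.60,-9.55,-9.53,100.10,NA,NA,
BBR,3c4c,2,0.60,-8.44,-8.40,647.30,NA,NA,
BBR,3og7,1,0.60,-7.78,-7.76,1980,NA,NA,
BBR,3psd,1,0.60,-8.60,-8.59,497.24,NA,NA,
BBR-2,1uwh,2,1.79,-8.98,-8.67,262.81,331,6.48,
BBR-2,1uwj,3,1.79,-10.38,-9.29,24.36,NA,NA,printed lowest Ki outside the interval implied by the printed lowest energy at 2-decimal precision (24.42-24.84 nM)
BBR-2,3c4c,2,1.79,-9.44,-8.93,119.66,NA,NA,
BBR-2,3og7,1,1.79,-8.71,-8.57,412.95,NA,NA,
BBR-2,3psd,1,1.79,-9.81,-9.61,64.85,NA,NA,
BBR-3,1uwh,3,1.49,-8.43,-8.10,658.29,1258,5.90,
BBR-3,1uwj,2,1.49,-10.61,-9.77,16.71,NA,NA,mean energy printed with a sign typo in the source (+9.77); stored as -9.77
BBR-3,3c4c,4,1.49,-9.14,-8.44,198.67,NA,NA,
BBR-3,3og7,4,1.49,-7.80,-7.40,1920,NA,NA,
BBR-3,3psd,1,1.49,-9.46,-9.33,116.92,NA,NA,
BBR-4,1uwh,2,0.60,-8.05,-7.97,1260,1549,5.81,
BBR-4,1uwj,1,0.60,-8.97,-8.96,264.39,NA,NA,
BBR-4,3c4c,2,0.60,-7.92,-7.82,1570,NA,NA,
BBR-4,3og7,1,0.60,-7.47,-7.45,3370,NA,NA,
BBR-4,3psd,1,0.60,-8.59,-8.57,507.28,NA,NA,
BBR-5,1uwh,1,0.60,-8.71,-8.67,412.15,776,6.11,
BBR-5,1uwj,1,0.60,-9.27,-9.25,159.96,NA,NA,
BBR-5,3c4c,2,0.60,-7.91,-7.90,1580,NA,NA,
BBR-5,3og7,1,0.60,-7.96,-7.78,1460,NA,NA,
BBR-5,3psd,1,0.60,-8.60,-8.80,352.40,NA,NA,printed lowest and mean energies transposed (lowest > mean); printed Ki matches the mean-energy column
BBR-6,1uwh,2,0.89,-9.22,-9.04,175.09,380,6.42,
BBR-6,1uwj,1,0.89,-10.89,-10.13,36.40,NA,NA,printed Ki corresponds to -10.15 kcal/mol and matches neither printed energy column
BBR-6,3c4c,2,0.89,-8.95,-8.72,274.99,NA,NA,
BBR-6,3og7,1,0.89,-8.21,-8.21,855.04,NA,NA,printed Ki corresponds to -8.28 kcal/mol rather than the printed -8.21
BBR-6,3psd,2,0.89,-9.24,-9.20,167.57,NA,NA,
BBR-7,1uwh,3,1.49,-9.66,-8.81,82.32,246,6.60,
BBR-7,1uwj,2,1.49,-11.44,-10.71,4.14,NA,NA,
BBR-7,3c4c,2,1.49,-11.62,-11.16,3.03,NA,NA,
BBR-7,3og7,5,1.49,-10.46,-9.57,21.48,NA,NA,
BBR-7,3psd,6,1.49,-9.24,-8.5,168.34,NA,NA,
BBR-8,1uwh,2,0.89,-8.93,-8.68,283.94,617,6.21,
BBR-8,1uwj,1,0.89,-9.94,-9.92,51.72,NA,NA,
BBR-8,3c4c,1,0.89,-8.78,-8.76,368.26,NA,NA,
BBR-8,3og7,2,0.89,-7.94,-7.85,1520,NA,NA,
BBR-8,3psd,2,0.89,-8.93,-8.84,284.65,NA,NA,
BBR-9,1uwh,7,1.49,-10.14,-9.26,37.12,155,6.81,
BBR-9,1uwj,2,1.49,-10.64,-10.56,15.85,NA,NA,
BBR-9,3c4c,6,1.49,-9.96,-9.62,50.32,NA,NA,
BBR-9,3og7,3,1.49,-9.53,-9.41,103.08,NA,NA,
BBR-9,3psd,3,1.49,-10.11,-9.97,38.97,NA,NA,
BBR-10,1uwh,3,1.49,-9.20,-8.65,181.31,269,6.57,
BBR-10,1uwj,2,1.49,-11.01,-10.64,8.47,NA,NA,
BBR-10,3c4c,3,1.49,-9.54,-9.22,101.76,NA,NA,
BBR-10,3og7,3,1.49,-8.34,-8.35,365.89,NA,NA,printed lowest > mean; printed Ki corresponds to -8.72 kcal/mol and matches neither column
BBR-10,3psd,2,1.49,-9.87,-9.52,58.63,NA,NA,
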