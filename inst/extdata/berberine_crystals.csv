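target,crystal_id,conformation,phenotype,resolution_a
BRAF,1uwh,DFG-out,wild-type,2.95
BRAF,1uwj,DFG-out,mutated,3.5
BRAF,3c4c,DFG-in,mutated,2.57
BRAF,3og7,DFG-in,mutated,2.45
BRAF,3psd,DFG-in,wild-type,3.6
CRAF,3omv,DFG-in,wild-type,4.0
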