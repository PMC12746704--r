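# synthetic descriptor table: values constructed, not computed from wavefunctions
name,e_homo,e_lumo,unit,spin_density_C,q_neutral,q_radical
FA,-7.659355,-0.459355,eV,0.72,0.121,0.423
PA,-7.364278,-0.364278,eV,0.62,0.146,0.397
DA,-7.085274,-0.185274,eV,0.6,0.15,0.393
BnA,-6.317212,-0.517212,eV,0.42,0.132,0.304
FBnA,-6.442778,-0.742778,eV,0.45,0.158,0.354
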