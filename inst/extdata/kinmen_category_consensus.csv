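icpc_category,nur,nt,fic_printed
musculoskeletal,63,5,0.94
eye,31,4,0.90
respiratory,136,18,0.87
blood-blood-forming-lymph-spleen,50,10,0.82
general-unspecified,102,21,0.80
digestive,58,16,0.74
urological,18,7,0.65
female-genital-breast,3,2,0.50
endocrine-metabolic-nutritional,18,10,0.47
psychological,4,3,0.33
cardiovascular,1,1,0.00
male-genital,1,1,0.00
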