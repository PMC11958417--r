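hap_id,group,family,origin,n_offspring,alleles,lineages,class,nucl_p,aa_p,func_dist
H1,1,F1,mother,12,"17,71","B,B",B-only,0.143,0.238,15.39
H2,1,F1,mother,7,"31,50","A,C",AC,0.298,0.418,28.49
H3,1,F1,father1*,5,"21,70","B,B",B-only,0.164,0.338,21.26
H4,1,F1,father2*,6,"65,51","B,C",BC,0.324,0.481,36.43
H5,2,F2,mother1,5,"42,45","B,C",BC,0.366,0.544,36.32
H6,2,F2,mother1,6,"03,21","A,B",AB,0.193,0.350,23.68
H7,2,F4,mother3,1,"18,33","B,B",B-only,0.107,0.213,16.25
H8,2,F4,mother3,5,"72","B",B-only,NA,NA,NA
H9,2,F5,mother4,4,"11,17","A,B",AB,0.168,0.288,18.74
H10,2,F5,mother4,9,"06,55","A,C",AC,0.336,0.519,37.13
H11,2,"F2,F4,F5",father1,14,"35,41","B,B",B-only,0.127,0.238,17.59
H12,2,"F2,F3,F4,F5",father1,9,"03,16","A,B",AB,0.193,0.350,23.01
H13,2,"F2,F5",father3,5,"68,69","B,B",B-only,0.135,0.225,17.19
H14,2,F5,father3,3,"67,45","B,C",BC,0.311,0.456,28.90
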