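site,group,n_unmethylated,n_clones
+190,beta,13,17
+310,beta,11,17
+337,beta,11,17
+340,beta,14,17
+190,other,2,23
+310,other,0,23
+337,other,2,23
+340,other,1,23
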