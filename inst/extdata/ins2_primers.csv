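id,name,sequence,clamp,orientation,role
F1,Ins2-pro-For,GAGCTCGGACCATTAAGTGCCTTGCTGCCT,,forward,cloning
R1,Ins2-pro-Rev,CCATGGCTTGTGGGTCCTCCACTTCACG,,reverse,cloning
E1,Ins2-exon2-For,TTTTTGTTATTTTTAATTTAGTTTATTTTTTAGGTTATTG,,forward,mapping
E2,Ins2-exon2-Rev,ACAAAACTCACCTTATAAATCCTCCACTTCACA,,reverse,mapping
P1,Promoter-bisulfite-For,GTTTGGATTATTAAGTGTTTTGTTGTTTG,,forward,qBSP
P2,INS2-bisulfite-Rev1,ACCCACTAAAAAAAATACCTTCCTACTTAC,,reverse,qBSP
P3,INS2-bisulfite-Rev2,AACTTATAAATCCTCCACTTCACAACA,,reverse,qMSP
P4,1F Bisulf 5',TTTATTTTTGAGAGAGAGTTGGGGATTT,,forward,qMSP
P5,2F Bisulf 5',GATTTTAATTATTTTAGGATTAAGTAGAGGTGTTGAT,,forward,qMSP
P6,1R bisulf 5' rev,CTACCTAATAGTACAATACTAAATCTACAAAAAACA,,reverse,qMSP
P12,BS-INS2 pro-For1,GCAGGTTTTTATTTTTGAGAGAGAGTTGGGGATTT,GCAGG,forward,qMSP
P13,BS-INS2 pro-Rev1,CCTGCCAAACACTTCCCTAATACTAAATCTACAAAAAACA,CCTGCCAAACACTTCCC,reverse,qMSP
P16,BS-Pro-For,CAGGTTTTTATTTTTGAGAGAGAGTTGGGGA,CAGG,forward,qBSP
P17,BS-Pro-Rev,CCTGCCAAACACTTCCCTAATACTAAATCTACAAA,CCTGCCAAACACTTCCC,reverse,qBSP
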