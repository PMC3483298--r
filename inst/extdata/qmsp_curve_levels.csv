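log_copies,mean_cq,sd,cv_printed
1.2,34.82,2.98,8.5
1.7,33.54,2.52,7.5
2.2,31.87,3.69,11.6
2.7,30.22,3.44,11.4
3.1,28.97,2.82,9.7
3.6,26.89,3.24,12.1
4.1,25.44,3.00,11.8
4.6,23.42,2.87,12.2
5.0,22.00,2.71,12.3
5.5,20.20,2.71,13.4
6.0,18.28,2.67,14.6
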