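method,day,assay1,assay2,assay3,mean_printed,sd_printed,cv_printed
RER,1,0.610,0.541,1.068,0.739,0.286,38.72
RER,6,0.568,0.568,1.033,0.723,0.269,37.17
RER,7,0.650,0.654,0.984,0.763,0.192,25.13
RER,14,0.523,0.647,0.807,0.659,0.143,21.64
DI,1,1.398,0.408,0.491,0.766,0.549,71.67
DI,6,1.138,0.423,0.454,0.672,0.404,60.17
DI,7,1.496,0.504,0.410,0.803,0.601,74.85
DI,14,1.191,0.477,0.334,0.667,0.459,68.83
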