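reader,finding,tp,fp,tn,fn,sensitivity,specificity,accuracy
1,hemorrhage,7,0,105,0,100,100,100
1,parenchymal_change,32,0,71,2,94.11,100,98.09
1,dense_vessel,18,4,83,0,100,95.4,96.19
1,cta_occlusion,17,0,47,1,94.4,100,98.46
2,hemorrhage,7,0,105,0,100,100,100
2,parenchymal_change,33,0,71,1,97.05,100,99.04
2,dense_vessel,13,0,87,5,72.2,100,95.23
2,cta_occlusion,17,0,47,1,94.4,100,98.46
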