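set,model,tp,tn,fp,fn,npv,ppv,specificity,sensitivity,accuracy
training,fis_svm,759,238,385,65,78.5,66.3,38.2,92.1,68.9
training,lr,684,360,263,140,72.0,72.2,57.8,83.0,72.1
training,psa,792,52,571,32,61.9,58.1,8.3,96.1,58.3
training,psa_density,683,232,391,141,62.2,63.6,37.2,82.9,63.2
training,pirads,723,302,321,101,74.9,69.3,48.5,87.7,70.8
validation,fis_svm,108,17,45,11,60.7,70.6,27.4,90.8,69.1
validation,lr,93,28,34,26,51.9,73.2,45.2,78.2,66.9
validation,psa,108,4,58,11,26.7,65.1,6.5,90.8,61.9
validation,psa_density,96,19,43,23,45.2,69.1,30.6,80.7,63.5
validation,pirads,98,25,37,21,54.3,72.6,40.3,82.4,68.0
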