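activity,met,svm_gs,svm_gs_sd
sitting,1.5,105.2,77.5
standing,1.8,167.1,146.3
walking_3.2_kmh,2.5,826,236.1
walking_4.8_kmh,3.3,1353.3,246.2
walking_6.4_kmh,5,1875.3,438.4
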