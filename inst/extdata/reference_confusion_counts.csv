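modality,true_class,pred_class,count,true_total
srs,squamous_epithelium,tumor,112,1393
srs,tumor,squamous_epithelium,85,1138
srh,squamous_epithelium,tumor,58,1393
srh,tumor,squamous_epithelium,190,1138
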