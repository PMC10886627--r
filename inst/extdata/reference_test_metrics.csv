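class,modality,precision,recall,f1,n_tiles
stroma,srs,0.90,0.91,0.91,1035
adipose,srs,0.97,0.98,0.98,351
squamous_epithelium,srs,0.89,0.90,0.90,1393
muscle,srs,0.95,0.89,0.92,206
glandular,srs,0.92,0.82,0.87,607
tumor,srs,0.86,0.90,0.88,1138
stroma,srh,0.90,0.92,0.91,1035
adipose,srh,0.99,0.94,0.96,351
squamous_epithelium,srh,0.82,0.94,0.87,1393
muscle,srh,0.79,0.73,0.76,206
glandular,srh,0.96,0.85,0.90,607
tumor,srh,0.92,0.82,0.87,1138
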