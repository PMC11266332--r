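# Lesions detected per reader and condition (25 patients, one body region
# each). Reference condition: 0% reduction, penalisation factor 300.
# Transcribed from the published lesion-detectability table.
condition,reduction_pct,beta,reader,lesions_detected
0%-b300,0,300,1,76
0%-b300,0,300,2,77
17%-b450,17,450,1,74
17%-b450,17,450,2,73
33%-b450,33,450,1,67
33%-b450,33,450,2,68
50%-b600,50,600,1,68
50%-b600,50,600,2,58
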