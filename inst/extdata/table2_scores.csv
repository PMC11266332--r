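# Reader visual image-quality scores: marginal counts per score level
# (0 non-diagnostic, 1 poor, 2 moderate, 3 good), two readers, 25 patients
# per condition. Transcribed from the published reader-study score table.
condition,reduction_pct,beta,reader,score,count
0%-b300,0,300,1,0,0
0%-b300,0,300,1,1,0
0%-b300,0,300,1,2,17
0%-b300,0,300,1,3,8
0%-b300,0,300,2,0,0
0%-b300,0,300,2,1,0
0%-b300,0,300,2,2,3
0%-b300,0,300,2,3,22
17%-b450,17,450,1,0,0
17%-b450,17,450,1,1,0
17%-b450,17,450,1,2,10
17%-b450,17,450,1,3,15
17%-b450,17,450,2,0,0
17%-b450,17,450,2,1,1
17%-b450,17,450,2,2,2
17%-b450,17,450,2,3,22
33%-b450,33,450,1,0,0
33%-b450,33,450,1,1,0
33%-b450,33,450,1,2,19
33%-b450,33,450,1,3,6
33%-b450,33,450,2,0,0
33%-b450,33,450,2,1,1
33%-b450,33,450,2,2,9
33%-b450,33,450,2,3,15
50%-b600,50,600,1,0,0
50%-b600,50,600,1,1,0
50%-b600,50,600,1,2,13
50%-b600,50,600,1,3,12
50%-b600,50,600,2,0,0
50%-b600,50,600,2,1,5
50%-b600,50,600,2,2,17
50%-b600,50,600,2,3,3
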