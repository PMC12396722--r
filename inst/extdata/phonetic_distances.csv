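phoneme_1,phoneme_2,euclidean,cosine,jaccard,feature_edit
g,s,2.24,1,1,5
h,m,2.24,1,1,5
k,s,2,1,1,4
p,h,2,1,1,2
b,k,1.73,0.59,0.75,3
p,g,1.73,0.59,0.75,3
b,m,1.41,0.33,0.5,2
h,s,1.41,0.5,0.67,2
k,g,1,0.18,0.33,1
p,b,1,0.18,0.33,1
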