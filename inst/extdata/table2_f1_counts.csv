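line,n_female_marker_neg,n_female_marker_pos,n_male_marker_neg,n_male_marker_pos,chisq_published,published_digits
WT,102,103,103,99,0.1,1
SGyA,154,148,170,0,159.5,1
X-Cas9,0,267,273,243,263.6,1
Autosomal,232,0,193,0,432.2,1
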