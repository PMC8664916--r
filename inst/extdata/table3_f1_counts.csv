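line,n_female,n_male,chisq_published,published_digits
WT,249,247,0.01,2
SGyA,326,5,311.3,1
X-Cas9,0,200,200,0
Autosomal,0,0,NA,0
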