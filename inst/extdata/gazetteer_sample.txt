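toronto
vancouver
montreal
ottawa
calgary
edmonton
winnipeg
hamilton
mississauga
saskatoon
chicago
seattle
boston
houston
dallas
denver
atlanta
detroit
brooklyn
manhattan
greater london
new york
los angeles
san francisco
niagara falls
thunder bay
river bend
hell
buffalo
portland
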