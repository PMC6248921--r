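river
bend
hell
falls
bay
park
lake
hill
spring
springs
beach
forest
valley
grove
ridge
point
buffalo
portland
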