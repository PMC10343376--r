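pharmacophore,omitted,tp,tn
1,0,5,5417
1,1,53,5413
2,0,7,5417
2,1,97,5411
3,0,7,5417
3,1,96,5155
4,0,17,5416
4,1,134,5056
5,0,136,5338
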