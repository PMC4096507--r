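individual_id,total,cluster
wasp01,20,1
wasp02,8,2
wasp03,4,3
wasp04,28,1
wasp05,13,2
wasp06,7,3
wasp07,21,1
wasp08,29,2
wasp09,20,3
wasp10,18,1
wasp11,27,2
wasp12,10,3
wasp13,7,1
wasp14,28,2
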