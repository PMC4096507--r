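individual,taxonD,taxon01,taxon02,taxon03,taxon04,taxon05,taxon06,taxon07,taxon08,taxon09,taxon10,taxon11,taxon12,taxon14
wasp01,9,4,0,0,5,0,0,0,1,0,1,0,0,0
wasp02,2,0,4,0,0,1,0,0,1,0,0,0,0,0
wasp03,2,0,0,0,0,0,2,0,0,0,0,0,0,0
wasp04,4,12,0,1,6,0,1,2,0,0,2,0,0,0
wasp05,5,0,5,0,0,3,0,0,0,0,0,0,0,0
wasp06,2,0,1,2,0,0,2,0,0,0,0,0,0,0
wasp07,5,9,0,0,7,0,0,0,0,0,0,0,0,0
wasp08,6,0,16,0,0,7,0,0,0,0,0,0,0,0
wasp09,5,0,0,10,0,0,3,0,0,2,0,0,0,0
wasp10,3,13,0,0,2,0,0,0,0,0,0,0,0,0
wasp11,6,1,11,0,0,6,0,0,2,0,0,1,0,0
wasp12,5,0,0,3,0,0,1,0,0,1,0,0,0,0
wasp13,2,3,0,0,1,0,0,1,0,0,0,0,0,0
wasp14,9,0,12,0,0,3,0,0,1,0,0,1,1,1
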