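sample_id	group	ct_target	ct_reference
A01	A	24.4633832429245	20.2409231250055
A02	A	23.8137452425585	19.9509678554905
A03	A	23.8093616239222	20.0012143660739
A04	A	24.2736942167815	20.2463239010073
A05	A	24.2002818514473	19.9427967751181
A06	A	23.9594366363985	19.8595262195279
A07	A	24.2152425769877	20.2312759975514
A08	A	23.8297117451077	20.2374138231802
A09	A	24.4231665490274	20.0620289753514
A10	A	24.174624528722	20.2581631363981
A11	A	23.8387398996694	20.1239967695879
A12	A	23.533392875317	19.5992759960509
A13	A	23.9895645283202	20.2004345462886
A14	A	23.6572393454863	20.016334596451
A15	A	23.407323592879	19.6323061246951
A16	A	23.708236533749	19.6810697937578
A17	A	23.7530259345528	19.7995430882057
A18	A	23.9734886190012	20.0591399905573
A19	A	24.0559140281058	19.9823486639618
A20	A	23.5865769650357	20.1341679866291
B01	B	24.9553992054663	20.2311397861717
B02	B	25.2593671198183	20.1704688468227
B03	B	24.4774330372666	19.4928923081162
B04	B	25.0531432532803	19.8773898053052
B05	B	24.7232800454047	19.6894861810732
B06	B	25.4084042118889	20.1487421045142
B07	B	24.7967052778423	20.0498377931438
B08	B	24.772660036753	19.8881224968912
B09	B	25.1940332813258	20.1055053440439
B10	B	24.8211719383044	19.6912092522449
B11	B	24.7014621364252	19.8745398412593
B12	B	25.1091992545748	19.8240776853721
B13	B	24.5720250692059	19.938937791088
B14	B	25.097533075731	19.9708627215758
B15	B	25.2112513794382	20.0891178303312
B16	B	25.2469534469507	20.1977114059379
B17	B	24.8637443441212	20.0538764278765
B18	B	25.0440324212311	20.0044069257146
B19	B	25.2262869661371	19.9407046867146
B20	B	24.7712426504923	19.9414427957126
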