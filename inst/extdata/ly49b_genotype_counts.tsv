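population	sample_size	chrom	pos	id	n_minor_hom	n_het	n_major_hom
Australian Thoroughbred	156	6	38278097	rs68661802	0	66	90
Australian Thoroughbred	156	6	38278874	rs68663106	0	66	90
Japanese Thoroughbred	370	6	38278097	rs68661802	0	117	253
Japanese Thoroughbred	370	6	38278874	rs68663106	0	117	253
Swedish Warmblood	380	6	38278097	rs68661802	0	75	304
Swedish Warmblood	380	6	38278874	rs68663106	0	74	306
Coldblooded Trotter	646	6	38278097	rs68661802	0	258	388
Coldblooded Trotter	646	6	38278874	rs68663106	22	226	393
Quarter Horse	137	6	38278097	rs68661802	0	97	40
Quarter Horse	137	6	38278874	rs68663106	0	97	40
Exmoor Pony	285	6	38278097	rs68661802	0	1	279
Exmoor Pony	285	6	38278874	rs68663106	0	1	282
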