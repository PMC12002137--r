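name	locus	segment_type	anchor	reading_frame
IGHV1-1*01	IGH	V	285	0
IGHV2-1*01	IGH	V	291	0
IGHV3-1*01	IGH	V	288	0
IGHV4-1*01	IGH	V	294	0
IGHD1-1*01	IGH	D	NA	NA
IGHD2-1*01	IGH	D	NA	NA
IGHD3-1*01	IGH	D	NA	NA
IGHJ1*01	IGH	J	6	0
IGHJ2*01	IGH	J	8	2
IGHJ3*01	IGH	J	7	1
IGKV1-1*01	IGK	V	288	0
IGKV2-1*01	IGK	V	285	0
IGKJ1*01	IGK	J	5	2
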