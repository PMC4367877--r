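# goslim_generic_synthetic.txt
# A synthetic stand-in for the EBI generic GO-slim list: a curated set of
# broad, real GO accessions spanning the three namespaces, usable as a
# default slim vocabulary. For work against the current EBI generic slim,
# download that list and pass it via read_slim_terms() / --slim FILE.
# biological process
GO:0000003
GO:0002376
GO:0005975
GO:0006259
GO:0006260
GO:0006281
GO:0006355
GO:0006397
GO:0006412
GO:0006464
GO:0006629
GO:0006810
GO:0006914
GO:0006950
GO:0007049
GO:0007165
GO:0007275
GO:0009056
GO:0009058
GO:0016070
GO:0019538
GO:0023052
GO:0030154
GO:0032196
GO:0040007
GO:0048856
GO:0050896
GO:0051301
GO:0055085
# molecular function
GO:0001071
GO:0003677
GO:0003700
GO:0003723
GO:0003824
GO:0004672
GO:0005198
GO:0005215
GO:0008289
GO:0016301
GO:0016740
GO:0016787
GO:0030234
# cellular component
GO:0005576
GO:0005618
GO:0005634
GO:0005694
GO:0005737
GO:0005739
GO:0005773
GO:0005783
GO:0005794
GO:0005829
GO:0005840
GO:0005856
GO:0005886
GO:0009536
GO:0016020
GO:0031410
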