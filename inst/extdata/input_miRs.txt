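>ssc-let-7a
TGAGGTAGTAGGTTGTATAGTT
>ssc-miR-21
tagcttatcagactgatgttga
>hsa-miR-25-3p
CATTGCACTTGTCTCGGTCTGA
>ssc-mir30a-3p
CUUUCAGUCGGAUGUUUGCAGC
>ssc-miR-106a
AAAAGTGCTTACAGTGCAGGTAGC
>gga-miR146c-5p
UGAGAACUGAAUUCCAUGGACUG
>ssc-mir-148a-3p
TCAGTGCACTACAGAACTTTGT
>hsa-miR-223-3p
UGUCAGUUUGUCAAAUACCCCA
>mmu-miR-667-3p
ugacaccugccacccagcccaag
>ssc-miR-7134-3p
tgcggaacctgcggatacgg
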