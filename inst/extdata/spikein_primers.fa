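>spikein_C_fw
CGTTTCCGTTCTTCTTCGTC
>spikein_C_rv
TACTCGCACCGAAAATGTCA
>spikein_mC_fw
GTGGCGGGTTATGATGAACT
>spikein_mC_rv
CATAAAATGCGGGGATTCAC
>spikein_hmC_fw
TGAAAACGAAAGGGGATACG
>spikein_hmC_rv
GTCCAGCTGGGAGTCGATAC
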