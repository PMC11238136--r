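>donor_ssODN BRCA1 C-terminal HiBiT knock-in single-stranded oligo donor
TGCCAGGAGCTGGACACCTACCTGATACCCCAGATCCCCCACAGCCACTACGTCTCCGTGAGCGGCTGGCGGCTGTTCAAGAAGATTAGCTGACTGCAGCCAGCCACAGGTACAGAGCCACAGGACCCCAAGAATGAGCT
>insert_39bp linker + HiBiT tag coding sequence inserted before the stop codon
GTCTCCGTGAGCGGCTGGCGGCTGTTCAAGAAGATTAGC
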