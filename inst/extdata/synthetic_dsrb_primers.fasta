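>DSRp2060F|DSRp2060F/DSR4R|F
CAACATCGTYCAYACCCAGG
>DSR4R|DSRp2060F/DSR4R|R
GTGTAGCAGTTACCGCA
>DSR1728F-a|DSR1728Fmix/DSR4Rmix|F
ACARGGNTAYGGNTTCGA
>DSR1728F-b|DSR1728Fmix/DSR4Rmix|F
CCARGGHTAYGGCTTCGA
>DSR1728F-c|DSR1728Fmix/DSR4Rmix|F
GCAAGGCTATGGCTTCGA
>DSR4Rmix-a|DSR1728Fmix/DSR4Rmix|R
ATGTAGCNGTTACCRCA
>DSR4Rmix-b|DSR1728Fmix/DSR4Rmix|R
CTGTAGCAGTTACCRCA
>DSR1762F-a|DSR1762Fmix/DSR2107Rmix|F
ATGGNCAYACNATGRGCA
>DSR1762F-b|DSR1762Fmix/DSR2107Rmix|F
CTGGNCAYACNATGGGCA
>DSR1762F-c|DSR1762Fmix/DSR2107Rmix|F
GTGGACAYACAATGGGCA
>DSR2107R-a|DSR1762Fmix/DSR2107Rmix|R
AGGRTTNCCYTGACCGTA
>DSR2107R-b|DSR1762Fmix/DSR2107Rmix|R
CGGRTTHCCYTGACCGTA
>DSR2107R-c|DSR1762Fmix/DSR2107Rmix|R
GGGATTACCTTGACCGTA
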