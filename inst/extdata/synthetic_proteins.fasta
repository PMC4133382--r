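>SYNPROT0001 synthetic demo protein
TFALEVTRDEYDKVRDKEFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKNY
>SYNPROT0002 synthetic demo protein
FQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKYMLLAWTQQRGRMFSTTVCGGGYRCLNKA
>SYNPROT0003 synthetic demo protein
MQCCLFLTTFDQQAFDPMYTYEYMTKTPTDEYDKISDFPNAWFRGSLHKKDVRRYSAGMK
>SYNPROT0004 synthetic demo protein
PFMRCGAQDEYVCLEYRHTFYVKMGLKWKMWELTNGRKLVHQNWLFCDCQSEGYYMAQAE
>SYNPROT0005 synthetic demo protein
HNFVHPCDARYMKLHWVNLKWRQDYLCTVWEYLFPVWWLSCEHAQYWNWGNLHWCGKMGF
>SYNPROT0006 synthetic demo protein
KLTNAMEDGFLYCEYKQQDVLAIYFGQEKISYDQMCSQRTGWLPGAMPLPRTRIEGLYSN
>SYNPROT0007 synthetic demo protein
HDLLHWPLQMPDLWCHYMMAGLKNPVRAMDEYDGPDPSWSPPIPGGIFKLMAREHMLIDP
>SYNPROT0008 synthetic demo protein
DKSMPHVHFYVHTDSIWVLRNDYSLCIAPHMYDFCRFQFTVTVHPCNDYIYQAQVCFLND
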