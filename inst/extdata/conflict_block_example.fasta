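>t1
TACGGGACGA
>t2
TACGGGACGA
>t3
TTCGGGACTA
>t4
TTCGGGACTA
>t5
AAGGGGTCGA
>t6
AAGGGGTCGA
>t7
ATGGGGTCTA
>t8
ATCGGGTCTA
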