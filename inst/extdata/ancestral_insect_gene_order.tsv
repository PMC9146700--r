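name	strand
tRNA-Ile	light
tRNA-Gln	heavy
tRNA-Met	light
nd2	light
tRNA-Trp	light
tRNA-Cys	heavy
tRNA-Tyr	heavy
cox1	light
tRNA-Leu1	light
cox2	light
tRNA-Lys	light
tRNA-Asp	light
atp8	light
atp6	light
cox3	light
tRNA-Gly	light
nd3	light
tRNA-Ala	light
tRNA-Arg	light
tRNA-Asn	light
tRNA-Ser1	light
tRNA-Glu	light
tRNA-Phe	heavy
nd5	heavy
tRNA-His	heavy
nd4	heavy
nd4l	heavy
tRNA-Thr	light
tRNA-Pro	heavy
nd6	light
cytb	light
tRNA-Ser2	light
nd1	heavy
tRNA-Leu2	heavy
16S rRNA	heavy
tRNA-Val	heavy
12S rRNA	heavy
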