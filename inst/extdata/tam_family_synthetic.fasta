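>MERTK
ACDEFHKKLGNGERSTVWYACDEFHIKLMNPQASKVWYACDEFHIKLMNPQRETVWYACDEFHIKIMNPQRSTVWYACDE
FHIKVMLPFMSTGWYATDEFHIKLMNPQRSTVWYACDEFHIKLMNPQRSTVWYACDEFHIKLMNPMRSTVWYACDEDHIK
L
>TYRO3
ACDEFHKKLGNGERSTVWYACDEFHIKLMNPQASKVWYACDEFHIKLMNPQRETVWYACDEFHIKAMNPQRSTVWYACDE
FHIKVMLPFMSTGWYATDEFHIKLMNPQRSTVWYACDEFHIKLMNPQRSTVWYACDEFHIKLMNPMRSTVWYACDEDHIK
L
>AXL
ACDEFHKKLGNGERSTVWYACDEFHIKLMNPQASKVWYACDEFHIKLMNPQRETVWYACDEFHIKMMNPQRSTVWYACDE
FHIKVMLPFMSTGWYATDEFHIKLMNPQRSTVWYACDEFHIKLMNPQRSTVWYACDEFHIKLMNPMRSTVWYACDEDHIK
L
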