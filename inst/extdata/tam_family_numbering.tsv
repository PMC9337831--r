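id	first_resno
MERTK	585
TYRO3	516
AXL	534
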