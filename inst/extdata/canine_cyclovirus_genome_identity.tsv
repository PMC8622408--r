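label	CN9E	CN16E	CN34
CN9E	100	59.704	59.642
CN16E	59.704	100	99.790
CN34	59.642	99.790	100
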