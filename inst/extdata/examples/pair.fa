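>demo_pattern_synthetic
HFTNNHNNRVTFKAMQSILVFGGVQEIIHCTKNHNIVRAMSFKWPWTKRHICFRWPCNLHIEVTGVIDDY
>demo_subject_synthetic
HDTNSPNDNVTFKAMVPILVAGGVQEIIHCEKNCNIVAQSFKWPPHKHHICFTWPCNLHWEVTGVIDDY
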