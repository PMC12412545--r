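label,twotheta_deg
1-10,14.9
110,16.7
012,20.5
200,22.9
004,34.5
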