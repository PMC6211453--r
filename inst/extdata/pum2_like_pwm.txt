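A	0.01	0.01	0.01	0.97	0.25	0.97	0.01	0.97
C	0.01	0.01	0.01	0.01	0.25	0.01	0.01	0.01
G	0.01	0.97	0.01	0.01	0.25	0.01	0.01	0.01
T	0.97	0.01	0.97	0.01	0.25	0.01	0.97	0.01
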