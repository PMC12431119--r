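LD2,O1,O2,+1,+2,D1,D2,D3
O1,O,O,O,O,O,D,D
O2,O,O,O,D,D,D,D
+1,+,+,+,+,D,D,D
+2,+,+,+,+,+,D,D
D1,O,O,O,D,D,D,D
D2,O,O,O,D,D,D,D
D3,O,+,+,+,+,D,D
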