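helix	start	end
1	28	57
2	62	91
3	96	125
4	130	159
5	164	193
6	198	227
7	232	261
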