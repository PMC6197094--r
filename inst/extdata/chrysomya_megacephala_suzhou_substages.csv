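substage,temperature_C,min_h,max_h
A,16,0,16
A,22,0,8
A,28,0,8
A,34,0,0
B,16,8,24
B,22,8,16
B,28,8,16
B,34,8,8
C,16,24,40
C,22,16,24
C,28,8,16
C,34,8,16
D,16,32,64
D,22,24,48
D,28,16,24
D,34,16,16
E,16,56,72
E,22,40,56
E,28,24,32
E,34,16,24
F,16,72,112
F,22,48,72
F,28,32,40
F,34,24,40
G,16,104,200
G,22,64,112
G,28,40,64
G,34,32,48
H,16,176,224
H,22,104,128
H,28,72,80
H,34,48,56
I,16,208,232
I,22,128,144
I,28,80,88
I,34,64,72
J,16,224,280
J,22,136,160
J,28,80,104
J,34,64,80
K,16,272,344
K,22,160,184
K,28,96,112
K,34,80,96
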