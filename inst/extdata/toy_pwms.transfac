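ID zld
P0 A C G T
01 8 1 0 1
02 0 0 9 1
03 9 0 1 0
04 0 1 0 9
05 1 8 1 0
06 3 3 2 2
CC core=0
//
ID kr
P0 A C G T
01 10  0  0  0
02  0  0  0 10
03  0  0 10  0
04 10  0  0  0
05  0 10  0  0
06 5 2 2 1
07 4 3 2 1
CC core=0
//
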