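VV  synthetic GC-rich zinc-finger-like motif, 14 bp; constructed fixture,
VV  NOT a TRANSFAC database matrix
XX
ID  M_SYNGC1
BF  synthetic
P0      A      C      G      T
01      6      3      3     11
02      2      2     17      2
03      2     17      2      2
04      1      1     20      1
05      1      1     20      1
06      1      1     20      1
07      1      1     20      1
08      1      1     20      1
09      1      1     20      1
10      1      1     20      1
11      2     17      2      2
12      2      2     17      2
13      3      3      7     10
14      3      3     10      7
CC  core: 6-10
XX
//
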