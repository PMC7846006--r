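label	parent	snps
H2a2a1	NA	NA
H	H2a2a1	263A>G
H1	H	3010G>A
H7	H	4793A>G
H7b	H7	5348C>T
R	H2a2a1	73A>G,2706A>G,7028C>T,11719G>A,14766C>T
J	R	295C>T,489T>C
N1	R	199T>C,204T>C,16223C>T,10238T>C
I	N1	203G>A,10034T>C,16129G>A,16391G>A
I1	I	3447A>G,10915T>C,16172T>C
I1a	I1	1719G>A,6734G>A
I1a1b	I1a	3990C>T,4529A>T,8251G>A,9947G>A,10398A>G,12501G>A,12705C>T,13780A>G,14182T>C,15043G>A,15924A>G,16311T>C
U	R	263A>G,11467A>G,12308A>G,12372G>A
K	U	1189T>C,10550A>G
U2	U	508A>G,16051A>G
U2e	U2	3720A>G,5390A>G,6045C>T,6152T>C,16129G>C,16189T>C
U2e2	U2e	152T>C,195T>C,217T>C,1811A>G
U2e2a	U2e2	3849G>A,4553T>C,4736T>C,5426T>C
U2e2a1	U2e2a	8473T>C,10876A>G,12557C>T,13020T>C,13734T>C,15907A>G,16362T>C
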