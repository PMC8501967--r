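scaffold_base,role,residue,atom,element,x,y,z
A,scaffold,DA,P,P,5.4836,-3.1675,0.7776
A,scaffold,DA,OP1,O,5.9121,-2.6732,-0.5497
A,scaffold,DA,OP2,O,4.4278,-4.3678,0.5886
A,scaffold,DA,O5',O,4.7926,-1.9684,1.5992
A,scaffold,DA,C5',C,4.2776,-1.0495,0.6348
A,scaffold,DA,C4',C,5.262,0.1077,0.4551
A,scaffold,DA,O4',O,4.6584,1.1816,-0.3022
A,scaffold,DA,C3',C,5.5889,0.7637,1.8202
A,scaffold,DA,O3',O,6.442,-0.0765,2.5999
A,scaffold,DA,C2',C,6.0199,2.1885,1.3995
A,scaffold,DA,C1',C,5.402,2.3724,0.0004
A,scaffold,DA,N9,N,4.5059,3.532,0.0
A,scaffold,DA,C8,C,4.8821,4.8409,0.0012
A,scaffold,DA,N7,N,3.8294,5.6058,0.0018
A,scaffold,DA,C5,C,2.7133,4.8381,-0.0048
A,scaffold,DA,C6,C,1.3333,5.0997,0.0015
A,scaffold,DA,N6,N,0.8592,6.3999,0.0028
A,scaffold,DA,N1,N,0.4931,4.0698,0.0009
A,scaffold,DA,C2,C,0.9363,2.8272,0.0005
A,scaffold,DA,N3,N,2.2191,2.5337,0.0002
A,scaffold,DA,C4,C,3.1347,3.4975,0.0009
A,partner,DT,P,P,-5.4836,-3.1675,-0.7776
A,partner,DT,OP1,O,-5.9121,-2.6732,0.5497
A,partner,DT,OP2,O,-4.4278,-4.3678,-0.5886
A,partner,DT,O5',O,-4.7926,-1.9684,-1.5992
A,partner,DT,C5',C,-4.2776,-1.0495,-0.6348
A,partner,DT,C4',C,-5.262,0.1077,-0.4551
A,partner,DT,O4',O,-4.6584,1.1816,0.3022
A,partner,DT,C3',C,-5.5889,0.7637,-1.8202
A,partner,DT,O3',O,-6.442,-0.0765,-2.5999
A,partner,DT,C2',C,-6.0199,2.1885,-1.3995
A,partner,DT,C1',C,-5.402,2.3724,-0.0004
A,partner,DT,N1,N,-4.5059,3.4305,-0.0
A,partner,DT,C2,C,-3.1099,3.2231,0.0002
A,partner,DT,O2,O,-2.5819,2.1096,-0.0001
A,partner,DT,N3,N,-2.3379,4.3895,0.0005
A,partner,DT,C4,C,-2.8012,5.6965,-0.0003
A,partner,DT,O4,O,-2.0644,6.6786,-0.0012
A,partner,DT,C5,C,-4.282,5.8344,0.0005
A,partner,DT,C7,C,-4.8603,7.213,0.0009
A,partner,DT,C6,C,-5.0241,4.7193,0.0002
T,scaffold,DT,P,P,5.4836,-3.1675,0.7776
T,scaffold,DT,OP1,O,5.9121,-2.6732,-0.5497
T,scaffold,DT,OP2,O,4.4278,-4.3678,0.5886
T,scaffold,DT,O5',O,4.7926,-1.9684,1.5992
T,scaffold,DT,C5',C,4.2776,-1.0495,0.6348
T,scaffold,DT,C4',C,5.262,0.1077,0.4551
T,scaffold,DT,O4',O,4.6584,1.1816,-0.3022
T,scaffold,DT,C3',C,5.5889,0.7637,1.8202
T,scaffold,DT,O3',O,6.442,-0.0765,2.5999
T,scaffold,DT,C2',C,6.0199,2.1885,1.3995
T,scaffold,DT,C1',C,5.402,2.3724,0.0004
T,scaffold,DT,N1,N,4.5059,3.4305,0.0
T,scaffold,DT,C2,C,3.1099,3.2231,-0.0002
T,scaffold,DT,O2,O,2.5819,2.1096,0.0001
T,scaffold,DT,N3,N,2.3379,4.3895,-0.0005
T,scaffold,DT,C4,C,2.8012,5.6965,0.0003
T,scaffold,DT,O4,O,2.0644,6.6786,0.0012
T,scaffold,DT,C5,C,4.282,5.8344,-0.0005
T,scaffold,DT,C7,C,4.8603,7.213,-0.0009
T,scaffold,DT,C6,C,5.0241,4.7193,-0.0002
T,partner,DA,P,P,-5.4836,-3.1675,-0.7776
T,partner,DA,OP1,O,-5.9121,-2.6732,0.5497
T,partner,DA,OP2,O,-4.4278,-4.3678,-0.5886
T,partner,DA,O5',O,-4.7926,-1.9684,-1.5992
T,partner,DA,C5',C,-4.2776,-1.0495,-0.6348
T,partner,DA,C4',C,-5.262,0.1077,-0.4551
T,partner,DA,O4',O,-4.6584,1.1816,0.3022
T,partner,DA,C3',C,-5.5889,0.7637,-1.8202
T,partner,DA,O3',O,-6.442,-0.0765,-2.5999
T,partner,DA,C2',C,-6.0199,2.1885,-1.3995
T,partner,DA,C1',C,-5.402,2.3724,-0.0004
T,partner,DA,N9,N,-4.5059,3.532,-0.0
T,partner,DA,C8,C,-4.8821,4.8409,-0.0012
T,partner,DA,N7,N,-3.8294,5.6058,-0.0018
T,partner,DA,C5,C,-2.7133,4.8381,0.0048
T,partner,DA,C6,C,-1.3333,5.0997,-0.0015
T,partner,DA,N6,N,-0.8592,6.3999,-0.0028
T,partner,DA,N1,N,-0.4931,4.0698,-0.0009
T,partner,DA,C2,C,-0.9363,2.8272,-0.0005
T,partner,DA,N3,N,-2.2191,2.5337,-0.0002
T,partner,DA,C4,C,-3.1347,3.4975,-0.0009
G,scaffold,DG,P,P,5.4836,-3.1675,0.7776
G,scaffold,DG,OP1,O,5.9121,-2.6732,-0.5497
G,scaffold,DG,OP2,O,4.4278,-4.3678,0.5886
G,scaffold,DG,O5',O,4.7926,-1.9684,1.5992
G,scaffold,DG,C5',C,4.2776,-1.0495,0.6348
G,scaffold,DG,C4',C,5.262,0.1077,0.4551
G,scaffold,DG,O4',O,4.6584,1.1816,-0.3022
G,scaffold,DG,C3',C,5.5889,0.7637,1.8202
G,scaffold,DG,O3',O,6.442,-0.0765,2.5999
G,scaffold,DG,C2',C,6.0199,2.1885,1.3995
G,scaffold,DG,C1',C,5.402,2.3724,0.0004
G,scaffold,DG,N9,N,4.5226,3.7715,0.0
G,scaffold,DG,C8,C,5.0033,5.0479,-0.0003
G,scaffold,DG,N7,N,4.0133,5.8929,0.0008
G,scaffold,DG,C5,C,2.842,5.211,0.0018
G,scaffold,DG,C6,C,1.4799,5.5923,0.0031
G,scaffold,DG,O6,O,1.1611,6.7687,0.0037
G,scaffold,DG,N1,N,0.5421,4.6202,-0.0036
G,scaffold,DG,C2,C,0.9096,3.3087,0.0019
G,scaffold,DG,N2,N,-0.0651,2.3434,0.0029
G,scaffold,DG,N3,N,2.1714,2.9416,0.002
G,scaffold,DG,C4,C,3.1565,3.8468,0.0001
G,partner,DC,P,P,-5.4836,-3.1675,-0.7776
G,partner,DC,OP1,O,-5.9121,-2.6732,0.5497
G,partner,DC,OP2,O,-4.4278,-4.3678,-0.5886
G,partner,DC,O5',O,-4.7926,-1.9684,-1.5992
G,partner,DC,C5',C,-4.2776,-1.0495,-0.6348
G,partner,DC,C4',C,-5.262,0.1077,-0.4551
G,partner,DC,O4',O,-4.6584,1.1816,0.3022
G,partner,DC,C3',C,-5.5889,0.7637,-1.8202
G,partner,DC,O3',O,-6.442,-0.0765,-2.5999
G,partner,DC,C2',C,-6.0199,2.1885,-1.3995
G,partner,DC,C1',C,-5.402,2.3724,-0.0004
G,partner,DC,N1,N,-4.5226,3.1732,-0.0
G,partner,DC,C2,C,-3.2117,2.8746,0.0005
G,partner,DC,O2,O,-2.8626,1.7055,0.0025
G,partner,DC,N3,N,-2.2879,3.8342,-0.0003
G,partner,DC,C4,C,-2.6392,5.1127,-0.0016
G,partner,DC,N4,N,-1.6766,6.0957,-0.0017
G,partner,DC,C5,C,-4.0057,5.4588,0.002
G,partner,DC,C6,C,-4.9324,4.4725,-0.0019
C,scaffold,DC,P,P,5.4836,-3.1675,0.7776
C,scaffold,DC,OP1,O,5.9121,-2.6732,-0.5497
C,scaffold,DC,OP2,O,4.4278,-4.3678,0.5886
C,scaffold,DC,O5',O,4.7926,-1.9684,1.5992
C,scaffold,DC,C5',C,4.2776,-1.0495,0.6348
C,scaffold,DC,C4',C,5.262,0.1077,0.4551
C,scaffold,DC,O4',O,4.6584,1.1816,-0.3022
C,scaffold,DC,C3',C,5.5889,0.7637,1.8202
C,scaffold,DC,O3',O,6.442,-0.0765,2.5999
C,scaffold,DC,C2',C,6.0199,2.1885,1.3995
C,scaffold,DC,C1',C,5.402,2.3724,0.0004
C,scaffold,DC,N1,N,4.5226,3.1732,0.0
C,scaffold,DC,C2,C,3.2117,2.8746,-0.0005
C,scaffold,DC,O2,O,2.8626,1.7055,-0.0025
C,scaffold,DC,N3,N,2.2879,3.8342,0.0003
C,scaffold,DC,C4,C,2.6392,5.1127,0.0016
C,scaffold,DC,N4,N,1.6766,6.0957,0.0017
C,scaffold,DC,C5,C,4.0057,5.4588,-0.002
C,scaffold,DC,C6,C,4.9324,4.4725,0.0019
C,partner,DG,P,P,-5.4836,-3.1675,-0.7776
C,partner,DG,OP1,O,-5.9121,-2.6732,0.5497
C,partner,DG,OP2,O,-4.4278,-4.3678,-0.5886
C,partner,DG,O5',O,-4.7926,-1.9684,-1.5992
C,partner,DG,C5',C,-4.2776,-1.0495,-0.6348
C,partner,DG,C4',C,-5.262,0.1077,-0.4551
C,partner,DG,O4',O,-4.6584,1.1816,0.3022
C,partner,DG,C3',C,-5.5889,0.7637,-1.8202
C,partner,DG,O3',O,-6.442,-0.0765,-2.5999
C,partner,DG,C2',C,-6.0199,2.1885,-1.3995
C,partner,DG,C1',C,-5.402,2.3724,-0.0004
C,partner,DG,N9,N,-4.5226,3.7715,-0.0
C,partner,DG,C8,C,-5.0033,5.0479,0.0003
C,partner,DG,N7,N,-4.0133,5.8929,-0.0008
C,partner,DG,C5,C,-2.842,5.211,-0.0018
C,partner,DG,C6,C,-1.4799,5.5923,-0.0031
C,partner,DG,O6,O,-1.1611,6.7687,-0.0037
C,partner,DG,N1,N,-0.5421,4.6202,0.0036
C,partner,DG,C2,C,-0.9096,3.3087,-0.0019
C,partner,DG,N2,N,0.0651,2.3434,-0.0029
C,partner,DG,N3,N,-2.1714,2.9416,-0.002
C,partner,DG,C4,C,-3.1565,3.8468,-0.0001
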