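letter,x1,y1,z1,x2,y2,z2,x3,y3,z3,x4,y4,z4
A,0,0,0,0.38,0,0,0.3534925400,0.3790743391,0, 0.66127213820,0.3740241966,-0.2228143060
B,0,0,0,0.38,0,0,0.4525074182,0.3730183297,0, 0.76257613891,0.3866115934,-0.2192546730
C,0,0,0,0.38,0,0,0.5465810358,0.3415417376,0, 0.86795389770,0.3701361034,-0.2007531964
D,0,0,0,0.38,0,0,0.6293024310,0.2867896405,0, 0.96796551749,0.3227232712,-0.1685707212
E,0,0,0,0.38,0,0,0.6950342776,0.2124933033,0, 1.05234077020,0.2461378116,-0.1249004299
F,0,0,0,0.38,0,0,0.3534925400,0.3790743391,0, 0.23848654216,0.3444601478,-0.3605211204
G,0,0,0,0.38,0,0,0.4525074182,0.3730183297,0, 0.35319129903,0.4661879451,-0.3547615132
H,0,0,0,0.38,0,0,0.5465810358,0.3415417376,0, 0.52474465339,0.5375304366,-0.3248254951
I,0,0,0,0.38,0,0,0.6293024310,0.2867896405,0, 0.72597501077,0.5330824094,-0.2727531564
J,0,0,0,0.38,0,0,0.6950342776,0.2124933033,0, 0.91949066407,0.4430961936,-0.2020931408
K,0,0,0,0.38,0,0,0.3534925400,0.3790743391,0,-0.02280932614,0.3261885607, 0.0000000000
L,0,0,0,0.38,0,0,0.4525074182,0.3730183297,0, 0.10017755351,0.5153688352, 0.0000000000
M,0,0,0,0.38,0,0,0.5465810358,0.3415417376,0, 0.31262967516,0.6409858240, 0.0000000000
N,0,0,0,0.38,0,0,0.6293024310,0.2867896405,0, 0.57641665265,0.6630915066, 0.0000000000
O,0,0,0,0.38,0,0,0.6950342776,0.2124933033,0, 0.83738478307,0.5648231681, 0.0000000000
P,0,0,0,0.38,0,0,0.3534925400,0.3790743391,0, 0.23848654216,0.3444601478, 0.3605211204
Q,0,0,0,0.38,0,0,0.4525074182,0.3730183297,0, 0.35319129903,0.4661879451, 0.3547615132
R,0,0,0,0.38,0,0,0.5465810358,0.3415417376,0, 0.52474465339,0.5375304366, 0.3248254951
S,0,0,0,0.38,0,0,0.6293024310,0.2867896405,0, 0.72597501077,0.5330824094, 0.2727531564
T,0,0,0,0.38,0,0,0.6950342776,0.2124933033,0, 0.91949066407,0.4430961936, 0.2020931408
U,0,0,0,0.38,0,0,0.3534925400,0.3790743391,0, 0.66127213820,0.3740241966, 0.2228143060
V,0,0,0,0.38,0,0,0.4525074182,0.3730183297,0, 0.76257613891,0.3866115934, 0.2192546730
W,0,0,0,0.38,0,0,0.5465810358,0.3415417376,0, 0.86795389770,0.3701361034, 0.2007531964
X,0,0,0,0.38,0,0,0.6293024310,0.2867896405,0, 0.96796551749,0.3227232712, 0.1685707212
Y,0,0,0,0.38,0,0,0.6950342776,0.2124933033,0, 1.05234077020,0.2461378116, 0.1249004299
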