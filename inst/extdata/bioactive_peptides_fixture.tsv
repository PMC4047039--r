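sequence	activities	source_id
AA	ACE-inhibitor	fixture
AR	ACE-inhibitor	fixture
AW	ACE-inhibitor	fixture
EK	ACE-inhibitor	fixture
EY	ACE-inhibitor	fixture
GM	ACE-inhibitor	fixture
GR	ACE-inhibitor	fixture
HK	ACE-inhibitor	fixture
IA	ACE-inhibitor	fixture
KE	ACE-inhibitor	fixture
KG	ACE-inhibitor	fixture
LF	ACE-inhibitor	fixture
LW	ACE-inhibitor	fixture
NF	ACE-inhibitor	fixture
NY	ACE-inhibitor	fixture
PR	ACE-inhibitor	fixture
QK	ACE-inhibitor	fixture
RL	ACE-inhibitor	fixture
TF	ACE-inhibitor	fixture
VE	ACE-inhibitor	fixture
VF	ACE-inhibitor	fixture
VK	ACE-inhibitor	fixture
VR	ACE-inhibitor	fixture
VPK	ACE-inhibitor	fixture
VPP	ACE-inhibitor	fixture
IPP	ACE-inhibitor	fixture
PLP	ACE-inhibitor	fixture
GPFPIIV	ACE-inhibitor	fixture
EMPFPK	ACE-inhibitor	fixture
YAEERYPIL	ACE-inhibitor	fixture
KA	ACE-inhibitor;inhibitor	fixture
KP	ACE-inhibitor;antioxidative	fixture
LY	ACE-inhibitor;antioxidative	fixture
VY	ACE-inhibitor;antioxidative	fixture
HL	ACE-inhibitor;antioxidative	fixture
LV	stimulating	fixture
LI	stimulating	fixture
LL	stimulating;inhibitor	fixture
LHT	antioxidative	fixture
LK	antioxidative	fixture
TY	antioxidative	fixture
EL	antioxidative	fixture
VA	inhibitor	fixture
EF	inhibitor;hypotensive	fixture
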