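name,role,mode,lo,hi,base_lo,base_hi,at,halfwidth,assignment
PO4,mineral,area,560,600,530,630,,,nu4 PO4 in apatite
CO3,mineral,area,860,880,,,,,nu2 CO3
CO3b,mineral,area,1409,1425,,,,,nu3 CO3
CI,mineral,area,1010,1030,,,,,crystallinity index surface (nu3 PO4 shoulder)
CO3PO4_num,mineral,peak_height,,,,,871,8,nu2 CO3 height for CO3/PO4 ratio
CO3PO4_den,mineral,peak_height,,,,,1017,8,nu3 PO4 height for CO3/PO4 ratio
CO3PO4b_num,mineral,peak_height,,,,,1415,8,nu3 CO3 height for CO3/PO4b ratio
CO3PO4b_den,mineral,peak_height,,,,,575,8,nu4 PO4 height for CO3/PO4b ratio
chitin,organic,area,1030,1160,,,,,chitin / keratin sulfur-group region
cholesterol,organic,area,2850,2935,,,,,C-H stretch (lipids; strong in cholesterol)
amideII,organic,area,1535,1556,,,,,amide II
amideI,organic,area,1631,1650,,,,,amide I
collagen,organic,area,1240,1310,,,,,amide III proxy for collagen
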