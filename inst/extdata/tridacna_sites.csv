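site_code,site_name,n
EFA,Efate,14
CHE,Chesterfield,19
HUO,Huon,38
SUR,Surprise,43
COO,Recif Cook,27
BEL,Belep,24
AST,Astrolabe,45
POU,Poum,45
PWE,Pouebo,45
BB,Beautemps-Beaupres,45
HIE,Hienghene,43
OUV,Ouvea,48
LIF,Lifou,46
VOH,Voh,47
TIG,Tiga,25
MAR,Mare,47
PB,Port-Bouquet,38
BOU,Bourail,46
KUA,Kuake,11
GOR,Goro,22
MER,Merlet,41
IP,Ile des Pins,42
CS,Corne Sud,41
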