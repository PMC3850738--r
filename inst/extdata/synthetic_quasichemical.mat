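#name SYN_QC_synthetic_quasichemical
#representative min_heavy_atom
#bins 0:5
ALA ALA 1 -0.69
ALA ARG 1 -0.27
ALA ASN 1 -0.3366666667
ALA ASP 1 -0.3366666667
ALA CYS 1 -0.7366666667
ALA GLN 1 -0.3366666667
ALA GLU 1 -0.3366666667
ALA GLY 1 -0.5433333333
ALA HIS 1 -0.3566666667
ALA ILE 1 -0.87
ALA LEU 1 -0.8233333333
ALA LYS 1 -0.31
ALA MET 1 -0.6966666667
ALA PHE 1 -0.7566666667
ALA PRO 1 -0.4633333333
ALA SER 1 -0.5166666667
ALA THR 1 -0.5233333333
ALA TRP 1 -0.51
ALA TYR 1 -0.4833333333
ALA VAL 1 -0.85
ARG ARG 1 0.55
ARG ASN 1 0.08333333333
ARG ASP 1 -0.3166666667
ARG CYS 1 -0.3166666667
ARG GLN 1 0.08333333333
ARG GLU 1 -0.3166666667
ARG GLY 1 -0.1233333333
ARG HIS 1 0.2633333333
ARG ILE 1 -0.45
ARG LEU 1 -0.4033333333
ARG LYS 1 0.51
ARG MET 1 -0.2766666667
ARG PHE 1 -0.3366666667
ARG PRO 1 -0.04333333333
ARG SER 1 -0.09666666667
ARG THR 1 -0.1033333333
ARG TRP 1 -0.09
ARG TYR 1 -0.06333333333
ARG VAL 1 -0.43
ASN ASN 1 0.01666666667
ASN ASP 1 0.01666666667
ASN CYS 1 -0.3833333333
ASN GLN 1 0.01666666667
ASN GLU 1 0.01666666667
ASN GLY 1 -0.19
ASN HIS 1 -0.003333333333
ASN ILE 1 -0.5166666667
ASN LEU 1 -0.47
ASN LYS 1 0.04333333333
ASN MET 1 -0.3433333333
ASN PHE 1 -0.4033333333
ASN PRO 1 -0.11
ASN SER 1 -0.1633333333
ASN THR 1 -0.17
ASN TRP 1 -0.1566666667
ASN TYR 1 -0.13
ASN VAL 1 -0.4966666667
ASP ASP 1 0.4166666667
ASP CYS 1 -0.3833333333
ASP GLN 1 0.01666666667
ASP GLU 1 0.4166666667
ASP GLY 1 -0.19
ASP HIS 1 -0.2033333333
ASP ILE 1 -0.5166666667
ASP LEU 1 -0.47
ASP LYS 1 -0.3566666667
ASP MET 1 -0.3433333333
ASP PHE 1 -0.4033333333
ASP PRO 1 -0.11
ASP SER 1 -0.1633333333
ASP THR 1 -0.17
ASP TRP 1 -0.1566666667
ASP TYR 1 -0.13
ASP VAL 1 -0.4966666667
CYS CYS 1 -0.7833333333
CYS GLN 1 -0.3833333333
CYS GLU 1 -0.3833333333
CYS GLY 1 -0.59
CYS HIS 1 -0.4033333333
CYS ILE 1 -0.9166666667
CYS LEU 1 -0.87
CYS LYS 1 -0.3566666667
CYS MET 1 -0.7433333333
CYS PHE 1 -0.8033333333
CYS PRO 1 -0.51
CYS SER 1 -0.5633333333
CYS THR 1 -0.57
CYS TRP 1 -0.5566666667
CYS TYR 1 -0.53
CYS VAL 1 -0.8966666667
GLN GLN 1 0.01666666667
GLN GLU 1 0.01666666667
GLN GLY 1 -0.19
GLN HIS 1 -0.003333333333
GLN ILE 1 -0.5166666667
GLN LEU 1 -0.47
GLN LYS 1 0.04333333333
GLN MET 1 -0.3433333333
GLN PHE 1 -0.4033333333
GLN PRO 1 -0.11
GLN SER 1 -0.1633333333
GLN THR 1 -0.17
GLN TRP 1 -0.1566666667
GLN TYR 1 -0.13
GLN VAL 1 -0.4966666667
GLU GLU 1 0.4166666667
GLU GLY 1 -0.19
GLU HIS 1 -0.2033333333
GLU ILE 1 -0.5166666667
GLU LEU 1 -0.47
GLU LYS 1 -0.3566666667
GLU MET 1 -0.3433333333
GLU PHE 1 -0.4033333333
GLU PRO 1 -0.11
GLU SER 1 -0.1633333333
GLU THR 1 -0.17
GLU TRP 1 -0.1566666667
GLU TYR 1 -0.13
GLU VAL 1 -0.4966666667
GLY GLY 1 -0.3966666667
GLY HIS 1 -0.21
GLY ILE 1 -0.7233333333
GLY LEU 1 -0.6766666667
GLY LYS 1 -0.1633333333
GLY MET 1 -0.55
GLY PHE 1 -0.61
GLY PRO 1 -0.3166666667
GLY SER 1 -0.37
GLY THR 1 -0.3766666667
GLY TRP 1 -0.3633333333
GLY TYR 1 -0.3366666667
GLY VAL 1 -0.7033333333
HIS HIS 1 0.07666666667
HIS ILE 1 -0.5366666667
HIS LEU 1 -0.49
HIS LYS 1 0.2233333333
HIS MET 1 -0.3633333333
HIS PHE 1 -0.4233333333
HIS PRO 1 -0.13
HIS SER 1 -0.1833333333
HIS THR 1 -0.19
HIS TRP 1 -0.1766666667
HIS TYR 1 -0.15
HIS VAL 1 -0.5166666667
ILE ILE 1 -1.05
ILE LEU 1 -1.003333333
ILE LYS 1 -0.49
ILE MET 1 -0.8766666667
ILE PHE 1 -0.9366666667
ILE PRO 1 -0.6433333333
ILE SER 1 -0.6966666667
ILE THR 1 -0.7033333333
ILE TRP 1 -0.69
ILE TYR 1 -0.6633333333
ILE VAL 1 -1.03
LEU LEU 1 -0.9566666667
LEU LYS 1 -0.4433333333
LEU MET 1 -0.83
LEU PHE 1 -0.89
LEU PRO 1 -0.5966666667
LEU SER 1 -0.65
LEU THR 1 -0.6566666667
LEU TRP 1 -0.6433333333
LEU TYR 1 -0.6166666667
LEU VAL 1 -0.9833333333
LYS LYS 1 0.47
LYS MET 1 -0.3166666667
LYS PHE 1 -0.3766666667
LYS PRO 1 -0.08333333333
LYS SER 1 -0.1366666667
LYS THR 1 -0.1433333333
LYS TRP 1 -0.13
LYS TYR 1 -0.1033333333
LYS VAL 1 -0.47
MET MET 1 -0.7033333333
MET PHE 1 -0.7633333333
MET PRO 1 -0.47
MET SER 1 -0.5233333333
MET THR 1 -0.53
MET TRP 1 -0.5166666667
MET TYR 1 -0.49
MET VAL 1 -0.8566666667
PHE PHE 1 -0.8233333333
PHE PRO 1 -0.53
PHE SER 1 -0.5833333333
PHE THR 1 -0.59
PHE TRP 1 -0.5766666667
PHE TYR 1 -0.55
PHE VAL 1 -0.9166666667
PRO PRO 1 -0.2366666667
PRO SER 1 -0.29
PRO THR 1 -0.2966666667
PRO TRP 1 -0.2833333333
PRO TYR 1 -0.2566666667
PRO VAL 1 -0.6233333333
SER SER 1 -0.3433333333
SER THR 1 -0.35
SER TRP 1 -0.3366666667
SER TYR 1 -0.31
SER VAL 1 -0.6766666667
THR THR 1 -0.3566666667
THR TRP 1 -0.3433333333
THR TYR 1 -0.3166666667
THR VAL 1 -0.6833333333
TRP TRP 1 -0.33
TRP TYR 1 -0.3033333333
TRP VAL 1 -0.67
TYR TYR 1 -0.2766666667
TYR VAL 1 -0.6433333333
VAL VAL 1 -1.01
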