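species,concentration_nM
I,100
IR,30
IRL,0
IRp,0
IRi,0
IRS,30
IRp-IRS,0
IRp-IRSp,0
PTP1B,10
PI3K,10
IRSp-PI3K,0
PIP2,200
PIP3,0
PTEN,10
AKT,100
pAKT,0
GSK3B,300
pGSK3B,0
IP3,0
DAG,0
Ins,0
PI,100
PIP,0
G,10
G-a,0
PKC,10
PKC-a,0
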