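transporter,gate,helices,residA,resnameA,residB,resnameB
EmrD,cytoplasmic,TM4-TM10,119,THR,311,PHE
EmrD,periplasmic,TM1-TM7,32,ALA,229,CYS
FucP,cytoplasmic,TM4-TM10,143,THR,370,SER
FucP,periplasmic,TM1-TM7,51,GLN,282,ILE
GlpT,cytoplasmic,TM4-TM10,138,TRP,368,ILE
GlpT,periplasmic,TM1-TM7,53,PRO,278,THR
LacY,cytoplasmic,TM4-TM10,126,GLU,333,CYS
LacY,periplasmic,TM1-TM7,32,ILE,245,ASN
NarU,cytoplasmic,TM4-TM10,149,MET,367,PHE
NarU,periplasmic,TM1-TM7,54,SER,273,ALA
NarK,cytoplasmic,TM4-TM10,151,MET,370,PHE
NarK,periplasmic,TM1-TM7,56,SER,275,ALA
PepT_So,cytoplasmic,TM4-TM10,131,SER,427,LEU
PepT_So,periplasmic,TM1-TM7,36,THR,320,SER
PepT_St,cytoplasmic,TM4-TM10,130,SER,407,GLY
PepT_St,periplasmic,TM1-TM7,34,ALA,303,SER
PiPT,cytoplasmic,TM4-TM10,154,ALA,439,ALA
PiPT,periplasmic,TM1-TM7,53,ASN,332,LEU
POT,cytoplasmic,TM4-TM10,138,ASN,420,GLY
POT,periplasmic,TM1-TM7,47,VAL,314,THR
XylE,cytoplasmic,TM4-TM10,149,MET,396,SER
XylE,periplasmic,TM1-TM7,32,SER,298,TYR
YajR,cytoplasmic,TM4-TM10,125,SER,328,SER
YajR,periplasmic,TM1-TM7,37,THR,236,PRO
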