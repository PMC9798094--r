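outcome,pt,records
DE,Cholestasis,9
DE,Drug-induced liver injury,13
DE,QT interval prolongation,12
DE,Renal impairment,20
LT,Cholestasis,3
LT,Drug-induced liver injury,7
LT,QT interval prolongation,18
LT,Renal impairment,6
HO,Cholestasis,47
HO,Drug-induced liver injury,35
HO,QT interval prolongation,33
HO,Renal impairment,31
DS,Drug-induced liver injury,1
DS,QT interval prolongation,1
DS,Renal impairment,3
RI,Cholestasis,1
RI,Drug-induced liver injury,1
RI,QT interval prolongation,1
OT,(unlisted),242
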