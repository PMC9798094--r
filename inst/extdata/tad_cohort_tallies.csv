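section,key,ae,ime
total,Total,10262,5563
drug,Fluconazole,1384,659
drug,Itraconazole,1154,629
drug,Voriconazole,3797,2372
drug,Posaconazole,2188,1166
drug,Isavuconazole,1739,737
outcome,DE,2240,1920
outcome,LT,365,296
outcome,HO,2791,1888
outcome,DS,193,108
outcome,CA,26,24
outcome,RI,11,9
outcome,OT,4440,3543
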