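raw_name,canonical,class
FLUCONAZOLE,fluconazole,TAD
DIFLUCAN,fluconazole,TAD
TRIFLUCAN,fluconazole,TAD
FLUCONAZOLUM,fluconazole,TAD
ITRACONAZOLE,itraconazole,TAD
SPORANOX,itraconazole,TAD
ONMEL,itraconazole,TAD
TOLSURA,itraconazole,TAD
VORICONAZOLE,voriconazole,TAD
VFEND,voriconazole,TAD
VORICONAZOLUM,voriconazole,TAD
POSACONAZOLE,posaconazole,TAD
NOXAFIL,posaconazole,TAD
POSANOL,posaconazole,TAD
ISAVUCONAZOLE,isavuconazole,TAD
CRESEMBA,isavuconazole,TAD
ISAVUCONAZONIUM,isavuconazole,TAD
ISAVUCONAZONIUM SULFATE,isavuconazole,TAD
AMPHOTERICIN B,amphotericin_b,non-TAD-antifungal
AMBISOME,amphotericin_b,non-TAD-antifungal
ABELCET,amphotericin_b,non-TAD-antifungal
FUNGIZONE,amphotericin_b,non-TAD-antifungal
CASPOFUNGIN,caspofungin,non-TAD-antifungal
CANCIDAS,caspofungin,non-TAD-antifungal
MICAFUNGIN,micafungin,non-TAD-antifungal
MYCAMINE,micafungin,non-TAD-antifungal
ANIDULAFUNGIN,anidulafungin,non-TAD-antifungal
ERAXIS,anidulafungin,non-TAD-antifungal
FLUCYTOSINE,flucytosine,non-TAD-antifungal
ANCOBON,flucytosine,non-TAD-antifungal
5-FLUOROCYTOSINE,flucytosine,non-TAD-antifungal
TERBINAFINE,terbinafine,non-TAD-antifungal
LAMISIL,terbinafine,non-TAD-antifungal
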