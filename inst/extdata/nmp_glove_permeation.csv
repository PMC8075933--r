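category_hint,material,brand,test_material,permeation_rate,nmp_concentration_mg_per_cm3,source
minimal,Refinishing gloves (natural rubber),Thompson & Forby,NMP Formulation IV,94,773,Stull et al.
minimal,Refinishing gloves (natural rubber),Thompson & Forby,Stripper IV-B,14,381,Stull et al.
minimal,Refinishing gloves (natural rubber),Thompson & Forby,NMP Formulation V,7.7,515,Stull et al.
minimal,Refinishing gloves (natural rubber),Thompson & Forby,Stripper IV-A,6.6,690,Stull et al.
minimal,Refinishing gloves (natural rubber),Thompson & Forby,NMP Formulation VI,0.19,371,Stull et al.
minimal,Nitrile,Kimberly-Clark Safeskin 52002M,NMP,>34,1030,Crook and Simpson
minimal,Nitrile,Ansell Solvex 37-675,NMP,32,1030,Crook and Simpson
minimal,Latex,Ansell Conform 69-150,NMP,>26,1030,Crook and Simpson
minimal,Latex,Ansell,NMP,39,1030,Zellers and Sulewski
minimal,Latex,Edmont Puretek,NMP,16,1030,Zellers and Sulewski
minimal,Latex/neoprene/nitrile,Pioneer Trionic,NMP,17,1030,Zellers and Sulewski
moderate,Polyethylene,Ansell Profood 35-405,Graffiti Gone CR-GR1,1.6,464,Crook and Simpson
moderate,Polyethylene,Ansell Profood 35-405,NMP,1.2,1030,Crook and Simpson
maximal,Butyl,North,Stripper IV-B,0.3,381,Stull et al.
maximal,Butyl,KCL Butoject 898,NMP,<0.1,1030,Crook and Simpson
maximal,Butyl,KCL Butoject 898,Graffiti Gone CR-GR1,<0.1,464,Crook and Simpson
maximal,Butyl,Comasec,NMP Formulation IV,<0.1,773,Stull et al.
maximal,Butyl,Comasec,NMP Formulation V,<0.1,515,Stull et al.
maximal,Butyl,Comasec,NMP Formulation VI,<0.1,371,Stull et al.
maximal,Butyl,Guardian,NMP Formulation IV,<0.1,773,Stull et al.
maximal,Butyl,Guardian,NMP Formulation V,<0.1,515,Stull et al.
maximal,Butyl,Guardian,NMP Formulation VI,<0.1,371,Stull et al.
maximal,Butyl,North,NMP Formulation IV,<0.1,773,Stull et al.
maximal,Butyl,North,NMP Formulation V,<0.1,515,Stull et al.
maximal,Butyl,North,NMP Formulation VI,<0.1,371,Stull et al.
maximal,Butyl,North,Stripper IV-A,<0.1,690,Stull et al.
maximal,Butyl,,NMP,nd,,Zellers and Sulewski
maximal,Laminate,North Silver Shield,NMP,<0.1,1030,Crook and Simpson
maximal,Laminate,North Silver Shield,Graffiti Gone CR-GR1,<0.1,464,Crook and Simpson
maximal,Laminate,Safety 4,NMP Formulation IV,<0.1,773,Stull et al.
maximal,Laminate,Safety 4,NMP Formulation V,<0.1,515,Stull et al.
maximal,Laminate,Safety 4,NMP Formulation VI,<0.1,371,Stull et al.
maximal,Laminate,Safety 4,Stripper IV-A,<0.1,690,Stull et al.
maximal,Laminate,Safety 4,Stripper IV-B,<0.1,381,Stull et al.
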