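name,centre,window_lo,window_hi,assignment,biomolecule_class,reference
fa_unsaturated,3011,2996,3026,nu(CH) from unsaturated fatty acids,storage,condensed-phase IR band compilations
fa_saturated_ch2_asym,2921,2906,2936,nu_as(C-H) of methylene (-CH2) from saturated fatty acids,storage,condensed-phase IR band compilations
fa_saturated_ch2_sym,2852,2837,2867,nu_s(C-H) of methylene (-CH2) from saturated lipids (CH stretch IV),storage,condensed-phase IR band compilations
lipid_ester_carbonyl,1744,1719,1769,nu(C=O) ester carbonyl of lipid triglycerides and fatty acids,storage,condensed-phase IR band compilations
protein_amide_ii,1549,1524,1574,protein amide II; mainly delta(N-H) of amides,functional,condensed-phase IR band compilations
carboxylate,1400,1375,1425,nu_s(COO-) from carboxylated molecules,functional,condensed-phase IR band compilations
phosphodiester,1241,1216,1266,nu_as(PO2-) of phosphodiester backbones of nucleic acids and phosphorylated molecules,functional,condensed-phase IR band compilations
carbohydrate,1168,1146,1191,nu_s(C-O) from carbohydrates,storage,condensed-phase IR band compilations
silica,1080,1055,1105,nu_s(Si-O) from biogenic silica,functional,condensed-phase IR band compilations
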