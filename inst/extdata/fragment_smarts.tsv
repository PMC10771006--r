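name	smarts
fr_carboxylic_acid	C(=O)[OX2H1]
fr_carboxylate	C(=O)[OX1-]
fr_ester	C(=O)O[#6]
fr_lactone	[#6R]C(=O)O[#6R]
fr_amide	C(=O)[NX3]
fr_primary_amide	C(=O)[NH2]
fr_lactam	[#6R]C(=O)[NX3R]
fr_ketone	[#6][CX3](=O)[#6]
fr_aldehyde	[CX3H1]=O
fr_ether	[OD2]([#6])[#6]
fr_alkyl_alcohol	[OX2H][CX4]
fr_phenol	[OX2H]c
fr_methoxy	[OX2][CH3]
fr_primary_amine	[NX3;H2;!$(NC=O);!$(N=*)]
fr_secondary_amine	[NX3;H1;!$(NC=O);!$(N=*)]
fr_tertiary_amine	[NX3;H0;!$(NC=O);!$(N=*);!$(N[O-])]
fr_quaternary_n	[NX4+]
fr_aniline_n	[NX3][c]
fr_nitrile	C#N
fr_nitro	[N+](=O)[O-]
fr_azo	[#6]N=N[#6]
fr_azide	N=[N+]=[N-]
fr_hydrazine	[NX3][NX3]
fr_hydrazone	C=N[NX3]
fr_imine	[CX3]=[NX2]
fr_oxime	C=NO
fr_guanidine	NC(=N)N
fr_amidine	[#6]C(=N)N
fr_urea	NC(=O)N
fr_carbamate	[OX2]C(=O)[NX3]
fr_thiol	[SX2H]
fr_thioether	[SX2]([#6])[#6]
fr_disulfide	[SX2][SX2]
fr_sulfoxide	[SX3]=[OX1]
fr_sulfone	[SX4](=O)(=O)[#6]
fr_sulfonamide	S(=O)(=O)[NX3]
fr_sulfonic_acid	S(=O)(=O)[OX2H,OX1-]
fr_sulfate_ester	OS(=O)(=O)O
fr_phosphate	[PX4](=O)
fr_phosphine	[PX3]
fr_thioamide	C(=S)N
fr_thiourea	NC(=S)N
fr_isocyanate	N=C=O
fr_isothiocyanate	N=C=S
fr_aryl_fluoride	cF
fr_aryl_chloride	cCl
fr_aryl_bromide	cBr
fr_aryl_iodide	cI
fr_alkyl_halide	[CX4][F,Cl,Br,I]
fr_trifluoromethyl	C(F)(F)F
fr_trichloromethyl	C(Cl)(Cl)Cl
fr_acyl_halide	C(=O)[F,Cl,Br,I]
fr_anhydride	C(=O)OC(=O)
fr_epoxide	C1OC1
fr_aziridine	C1NC1
fr_peroxide	[OX2][OX2]
fr_hydroxylamine	[NX3][OX2H]
fr_n_oxide	[#7+][OX1-]
fr_michael_acceptor	C=CC=O
fr_enol_ether	C=C[OX2]
fr_enamine	C=C[NX3]
fr_alkene	[CX3]=[CX3]
fr_alkyne	[CX2]#[CX2]
fr_allene	C=C=C
fr_acetal	[CX4]([OX2])([OX2])[#6]
fr_benzene_ring	c1ccccc1
fr_pyridine_ring	n1ccccc1
fr_pyrimidine_ring	n1cnccc1
fr_pyrazine_ring	n1ccncc1
fr_pyridazine_ring	n1ncccc1
fr_triazine_ring	n1cncnc1
fr_pyrrole_ring	[nH]1cccc1
fr_n_subst_pyrrole	[n;X3;H0]1cccc1
fr_furan_ring	o1cccc1
fr_thiophene_ring	s1cccc1
fr_imidazole_ring	n1ccnc1
fr_pyrazole_ring	n1nccc1
fr_oxazole_ring	o1cncc1
fr_isoxazole_ring	o1nccc1
fr_thiazole_ring	s1cncc1
fr_triazole_ring	n1nncc1
fr_tetrazole_ring	n1nnnc1
fr_aromatic_n	[nX2]
fr_aromatic_nh	[nH]
fr_aromatic_o	[o]
fr_aromatic_s	[s]
fr_aromatic_ch	[cH]
fr_biaryl_bond	c-!@c
fr_benzylic_ch2	[CH2](c)[#6]
fr_arom_ring_fusion	[cR2]
fr_saturated_n_ring	[NX3R][CX4R]
fr_piperidine_like	[NX3R]1[CX4R][CX4R][CX4R][CX4R][CX4R]1
fr_piperazine_like	[NX3R]1[CX4R][CX4R][NX3R][CX4R][CX4R]1
fr_morpholine_like	[NX3R]1[CX4R][CX4R][OX2R][CX4R][CX4R]1
fr_pyrrolidine_like	[NX3R]1[CX4R][CX4R][CX4R][CX4R]1
fr_cyclopropyl	[CX4R]1[CX4R][CX4R]1
fr_cyclobutyl	[CX4R]1[CX4R][CX4R][CX4R]1
fr_cyclopentyl	[CX4R]1[CX4R][CX4R][CX4R][CX4R]1
fr_cyclohexyl	[CX4R]1[CX4R][CX4R][CX4R][CX4R][CX4R]1
fr_spiro_like	[X4R2]
fr_ring_size3	[r3]
fr_ring_size4	[r4]
fr_ring_size5	[r5]
fr_ring_size6	[r6]
fr_ring_size7	[r7]
fr_ring_size8	[r8]
fr_tbutyl	C(C)(C)(C)C
fr_isopropyl	[CH](C)C
fr_long_chain	[CH2][CH2][CH2][CH2]
fr_halogen_any	[F,Cl,Br,I]
fr_hba_n	[$([N;+0;X3;v3]);!$(N[C,S]=O)]
fr_hbd_any	[$([N;!H0;v3,v4&+1]),$([O,S;H1;+0]),n&H1&+0]
fr_carbonyl_any	[CX3]=[OX1]
fr_alpha_halo_carbonyl	[F,Cl,Br,I][CX4]C(=O)
fr_aryl_ketone	c[CX3](=O)[#6]
fr_benzamide	cC(=O)[NX3]
fr_aryl_carboxyl	cC(=O)[OX2H1,OX1-]
fr_vinyl_halide	C=C[F,Cl,Br,I]
fr_gem_dihalide	[CX4]([F,Cl,Br,I])[F,Cl,Br,I]
fr_ortho_subst_arene	[cH0][cH0]
fr_charged_any	[+,-]
fr_zwitter_n_plus	[NX4+,NX3+]
fr_oxo_acid_like	[CX3](=O)[OX2H1]
fr_amino_acid_like	[NX3][CX4]C(=O)[OX2H1,OX1-]
fr_sugar_like	[OX2H][CX4][CX4][OX2H]
fr_steroid_like	[CR2][CR2][CR2]
fr_nitroso	[NX2]=[OX1]
fr_boronic_acid	B([OX2H])[OX2H]
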