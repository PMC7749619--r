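gene	gene_id	description	p_value	shared
Anxa1	301	Annexin A1	1,44E−04	FALSE
Apc	324	APC regulator of WNT signaling pathway	5,21E−05	FALSE
Atp1a3	478	Atpase Na+/K + transporting subunit alpha 3	5,67E−05	TRUE
B2m	567	Beta-2 microglobulin	1,18E−04	FALSE
Cacna1g	8913	Calcium voltage-gated channel subunit alpha1 G	1,68E−04	FALSE
Camk2a	815	Calcium/calmodulin-dependent protein kinase II alpha	7,83E−05	TRUE
Camk2b	816	Calcium/calmodulin-dependent protein kinase II, beta	1,28E−04	FALSE
Cask	8573	Calcium/calmodulin-dependent serine protein kinase	1,74E−04	FALSE
Cdh1	999	Cadherin 1	6,79E−05	FALSE
Cdkn1a	1026	Cyclin-dependent kinase inhibitor 1A	1,72E−04	FALSE
Cxcl12	6387	Chemokine ligand 12	4,12E−05	FALSE
Ddc	1644	Dopa decarboxylase	2,29E−04	FALSE
Dnm1	1759	Dynamin 1	6,97E−05	TRUE
Drd2	1813	Dopamine receptor D2	1,16E−04	FALSE
Erbb3	2065	Erb-b2 receptor tyrosine kinase 3	4,43E−05	FALSE
Fn1	2335	Fibronectin 1	5,25E−05	FALSE
Fos	2353	FBJ osteosarcoma oncogene	8,11E−05	FALSE
Gabra2	2555	GABA A receptor, subunit alpha 2	1,85E−04	FALSE
Gabrb3	2562	GABA A receptor, subunit beta 3	4,30E−05	TRUE
Gnai2	2771	G-protein subunit alpha i2	1,47E−04	FALSE
Gria1	2890	Glutamate ionotropic receptor AMPA type subunit 1	9,54E−05	TRUE
Hla-Dqb1	3119	Major histocompatibility complex, class II, DQ beta 1	3,15E−05	FALSE
Igf1	3479	Insulin-like growth factor 1	6,79E−05	FALSE
Jun	3725	Jun proto-oncogene	1,23E−04	FALSE
Kcnq2	3785	Potassium voltage-gated channel subfamily Q member 2	8,24E−05	FALSE
Kit	3815	KIT proto-oncogene receptor tyrosine kinase	2,45E−05	FALSE
Limk1	3984	LIM domain-containing, protein kinase	1,40E−04	FALSE
Lrp1	4035	Low-density lipoprotein receptor-related protein 1	2,19E−04	FALSE
Mapt	4137	Microtubule-associated protein tau	5,15E−07	FALSE
Mef2c	4208	Myocyte enhancer factor 2C	8,03E−05	FALSE
Nrp1	8829	Neuropilin 1	2,19E−04	FALSE
Pdgfb	5155	Platelet derived growth factor, B polypeptide	3,17E−05	FALSE
Plcb1	23236	Phospholipase C, beta 1	7,44E−05	FALSE
Plcb4	5332	Phospholipase C, beta 4	1,24E−04	FALSE
Prkar1b	5575	Protein kinase, camp-dependent regulatory, type I beta	2,15E−04	FALSE
Prkcd	5580	Protein kinase C, delta	9,55E−05	FALSE
Slc1a1	6505	Solute carrier family, member 1	2,19E−04	FALSE
Stat1	6772	Signal transducer and activator of transcription 1	1,88E−04	FALSE
Stx1a	6804	Syntaxin 1A	7,43E−05	FALSE
Tgfb2	7042	Transforming growth factor, beta 2	6,95E−05	FALSE
Tgfb3	7043	Transforming growth factor, beta 3	1,73E−04	FALSE
Th	7054	Tyrosine hydroxylase	7,06E−05	FALSE
Wnt5a	7474	Wnt family member 5A	1,55E−04	FALSE
Ywhaz	7534	Tyrosine 3-monooxygenase/tryptophan 5-monooxygenase activation protein zeta	1,29E−04	FALSE
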