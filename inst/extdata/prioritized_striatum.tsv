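gene	gene_id	description	p_value	shared
Atp1a3	478	Atpase Na+/K + transporting subunit alpha 3	1,83E−05	TRUE
Atxn2	6311	Ataxin 2	4,33E−05	FALSE
Bmpr2	659	Bone morphogenetic protein receptor, type II	1,88E−04	FALSE
Braf	673	Braf transforming gene	4,08E−05	FALSE
Cacna2d1	781	Calcium channel, voltage-dependent, alpha2/delta subunit 1	1,88E−04	FALSE
Camk2a	815	Calcium/calmodulin-dependent protein kinase II alpha	3,83E−05	TRUE
Cdkn1b	1027	Cyclin-dependent kinase inhibitor 1B	1,06E−04	FALSE
Dnm1	1759	Dynamin 1	3,08E−05	TRUE
Dnm2	1785	Dynamin 2	6,12E−05	FALSE
Drd2	1813	Dopamine receptor D2	4,73E−05	FALSE
Gabrb3	2562	GABA A receptor, subunit beta 3	1,34E−05	TRUE
Gria1	2890	Glutamate receptor, ionotropic, AMPA1 (alpha 1)	2,80E−05	TRUE
Hbegf	1839	Heparin-binding EGF-like growth factor	1,86E−04	FALSE
Hspa8	3312	Heat shock protein 8	1,99E−04	FALSE
Irf4	3662	Interferon regulatory factor 4	7,62E−05	FALSE
Kalrn	8997	Kalirin, rhogef kinase	2,20E−04	FALSE
Kcnj6	3763	Potassium inwardly rectifying channel subfamily J member 6	1,00E−04	FALSE
Kif1b	23095	Kinesin family member 1B	2,12E−04	FALSE
Mapk8	5599	Mitogen-activated protein kinase 8	2,13E−04	FALSE
Mef2c	4208	Myocyte enhancer factor 2C	1,39E−04	FALSE
Pafah1b1	5048	Platelet-activating factor acetylhydrolase, isoform 1b, subunit 1	1,11E−04	FALSE
Prkar2b	5577	Protein kinase, camp-dependent regulatory, type II beta	1,08E−04	FALSE
Scn1a	6323	Sodium channel, voltage-gated, type I, alpha	7,14E−05	FALSE
Scn1b	6324	Sodium channel, voltage-gated, type I, beta	8,34E−05	FALSE
Slc1a2	6506	Solute carrier family 1, member 2	1,18E−04	FALSE
Syn1	6853	Synapsin I	1,94E−04	FALSE
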