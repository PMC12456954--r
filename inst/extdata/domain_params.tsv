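# Residue counts, compartments and binding-site types per modeled domain.
# n_residues_3d: size used in the soluble (3D cubic-box) system, where the
#   receptor cores are replaced by the fluorescent proteins used in the
#   corresponding in vitro reconstitution (DsRed2 for AMPAR, eqFP670 for
#   NMDAR).  n_residues_2d: size used in the membrane (2D) system, where the
#   cores are the transmembrane receptor assemblies (UniProt-derived
#   reconstruction; editable).
# compartment applies in 2D mode; every domain is cytoplasmic in 3D mode.
domain	template	n_residues_3d	n_residues_2d	compartment	site_types
AMPAR_core	AMPAR_TARP4	936	3528	membrane	-
TARPc	AMPAR_TARP4	121	121	cytoplasm	PBM_TARP
NMDAR_core	NMDAR_GluN2Bc2	482	3300	membrane	-
GluN2Bc	NMDAR_GluN2Bc2	644	644	cytoplasm	PBM_GluN2B,CaMKII_site_GluN2B
PSD95_Npalm	PSD95	60	60	membrane	-
PSD95_PDZ1	PSD95	86	86	cytoplasm	PDZ
PSD95_PDZ2	PSD95	86	86	cytoplasm	PDZ
PSD95_PDZ3	PSD95	86	86	cytoplasm	PDZ
PSD95_SH3	PSD95	77	77	cytoplasm	-
PSD95_GK	PSD95	180	180	cytoplasm	-
CaMKII_hub	CaMKII	1680	1680	cytoplasm	-
CaMKII_kinase	CaMKII	274	274	cytoplasm	kinase_active
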