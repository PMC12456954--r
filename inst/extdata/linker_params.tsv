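# PSD-95 inter-domain linkers modeled as entropic Gaussian chains.
# n_link: number of linker residues between consecutive domains
# (UniProt-boundary reconstruction; editable).
name	domain_i	domain_j	n_link
npalm_pdz1	PSD95_Npalm	PSD95_PDZ1	13
pdz1_pdz2	PSD95_PDZ1	PSD95_PDZ2	4
pdz2_pdz3	PSD95_PDZ2	PSD95_PDZ3	63
pdz3_sh3	PSD95_PDZ3	PSD95_SH3	37
sh3_gk	PSD95_SH3	PSD95_GK	32
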