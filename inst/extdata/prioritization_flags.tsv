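gene	mirna	two_dbs	energy	rna22	direct_validation	near_miss
L1TD1	hsa-miR-1303	TRUE	TRUE	FALSE	FALSE	FALSE
SLITRK6	hsa-miR-199a-3p	TRUE	FALSE	TRUE	FALSE	FALSE
SLITRK6	hsa-miR-425-5p	FALSE	TRUE	FALSE	TRUE	FALSE
ST6GALNAC1	hsa-miR-335-5p	TRUE	TRUE	FALSE	FALSE	FALSE
TCEA3	hsa-miR-335-5p	TRUE	TRUE	FALSE	FALSE	FALSE
TCEA3	hsa-miR-1225-3p	TRUE	TRUE	FALSE	FALSE	FALSE
TCEA3	hsa-miR-1233-3p	TRUE	TRUE	TRUE	FALSE	TRUE
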