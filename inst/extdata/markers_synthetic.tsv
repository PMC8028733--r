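population	gene
t_cells	t_cells_m1
t_cells	t_cells_m2
t_cells	t_cells_m3
t_cells	t_cells_m4
t_cells	t_cells_m5
cd8_t_cells	cd8_t_cells_m1
cd8_t_cells	cd8_t_cells_m2
cd8_t_cells	cd8_t_cells_m3
cd8_t_cells	cd8_t_cells_m4
cd8_t_cells	cd8_t_cells_m5
cytotoxic_lymphocytes	cytotoxic_lymphocytes_m1
cytotoxic_lymphocytes	cytotoxic_lymphocytes_m2
cytotoxic_lymphocytes	cytotoxic_lymphocytes_m3
cytotoxic_lymphocytes	cytotoxic_lymphocytes_m4
cytotoxic_lymphocytes	cytotoxic_lymphocytes_m5
nk_cells	nk_cells_m1
nk_cells	nk_cells_m2
nk_cells	nk_cells_m3
nk_cells	nk_cells_m4
nk_cells	nk_cells_m5
b_lineage	b_lineage_m1
b_lineage	b_lineage_m2
b_lineage	b_lineage_m3
b_lineage	b_lineage_m4
b_lineage	b_lineage_m5
monocytic_lineage	monocytic_lineage_m1
monocytic_lineage	monocytic_lineage_m2
monocytic_lineage	monocytic_lineage_m3
monocytic_lineage	monocytic_lineage_m4
monocytic_lineage	monocytic_lineage_m5
myeloid_dendritic_cells	myeloid_dendritic_cells_m1
myeloid_dendritic_cells	myeloid_dendritic_cells_m2
myeloid_dendritic_cells	myeloid_dendritic_cells_m3
myeloid_dendritic_cells	myeloid_dendritic_cells_m4
myeloid_dendritic_cells	myeloid_dendritic_cells_m5
neutrophils	neutrophils_m1
neutrophils	neutrophils_m2
neutrophils	neutrophils_m3
neutrophils	neutrophils_m4
neutrophils	neutrophils_m5
endothelial_cells	endothelial_cells_m1
endothelial_cells	endothelial_cells_m2
endothelial_cells	endothelial_cells_m3
endothelial_cells	endothelial_cells_m4
endothelial_cells	endothelial_cells_m5
fibroblasts	fibroblasts_m1
fibroblasts	fibroblasts_m2
fibroblasts	fibroblasts_m3
fibroblasts	fibroblasts_m4
fibroblasts	fibroblasts_m5
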