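#' Radiomic feature catalog
#'
#' The pipeline emits a fixed catalog of 199 named features per lesion:
#' 111 static features (shape 14, first-order 22, GLCM 24, GLRLM 16,
#' GLSZM 16, GLDM 14, NGTDM 5) and 88 kinetic features (aggregate 10,
#' heterogeneity 21, textural-kinetic 57). The catalog is frozen so that
#' downstream tables always have the same columns in the same order.
#'
#' @param group Optional subset: one of `"static"`, `"kinetic"` or a family
#'   prefix (`"shape"`, `"fo"`, `"glcm"`, `"glrlm"`, `"glszm"`, `"gldm"`,
#'   `"ngtdm"`, `"kin_agg"`, `"kin_het"`, `"kin_tex"`).
#' @return Character vector of feature names.
#' @export
#' @examples
#' length(feature_catalog())          # 199
#' length(feature_catalog("static"))  # 111
feature_catalog <- function(group = NULL) {
  cat_all <- c(static_feature_catalog(), kinetic_feature_catalog())
  if (is.null(group)) return(cat_all)
  group <- match.arg(group, c("static", "kinetic", "shape", "fo", "glcm",
                              "glrlm", "glszm", "gldm", "ngtdm",
                              "kin_agg", "kin_het", "kin_tex"))
  switch(group,
         static  = static_feature_catalog(),
         kinetic = kinetic_feature_catalog(),
         cat_all[startsWith(cat_all, paste0(group, "_"))])
}

#' @rdname feature_catalog
#' @export
static_feature_catalog <- function() {
  shape <- paste0("shape_", c(
    "voxel_volume", "mesh_volume", "surface_area", "surface_volume_ratio",
    "sphericity", "compactness", "spherical_disproportion",
    "max_3d_diameter", "major_axis_length", "minor_axis_length",
    "least_axis_length", "elongation", "flatness", "extent"))
  fo <- paste0("fo_", c(
    "mean", "median", "min", "max", "range", "p10", "p90", "iqr",
    "variance", "mad", "rmad", "rms", "energy", "total_energy",
    "entropy", "uniformity", "skewness", "kurtosis",
    "mean_pre", "mean_post1", "mean_post2", "mean_post3"))
  glcm <- paste0("glcm_", c(
    "autocorrelation", "joint_average", "cluster_prominence",
    "cluster_shade", "cluster_tendency", "contrast", "correlation",
    "difference_average", "difference_entropy", "difference_variance",
    "id", "idm", "idmn", "idn", "imc1", "imc2", "inverse_variance",
    "joint_energy", "joint_entropy", "max_probability", "mcc",
    "sum_average", "sum_entropy", "sum_squares"))
  glrlm <- paste0("glrlm_", c(
    "sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv", "rv", "re",
    "lglre", "hglre", "srlgle", "srhgle", "lrlgle", "lrhgle"))
  glszm <- paste0("glszm_", c(
    "sae", "lae", "gln", "glnn", "szn", "sznn", "zp", "glv", "zv", "ze",
    "lglze", "hglze", "salgle", "sahgle", "lalgle", "lahgle"))
  gldm <- paste0("gldm_", c(
    "sde", "lde", "gln", "dn", "dnn", "glv", "dv", "de",
    "lgle", "hgle", "sdlgle", "sdhgle", "ldlgle", "ldhgle"))
  ngtdm <- paste0("ngtdm_", c(
    "coarseness", "contrast", "busyness", "complexity", "strength"))
  c(shape, fo, glcm, glrlm, glszm, gldm, ngtdm)
}

#' @rdname feature_catalog
#' @export
kinetic_feature_catalog <- function() {
  agg <- paste0("kin_agg_", c(
    "wis_mean", "wis_sd", "wos_mean", "wos_sd", "pe_mean", "pe_sd",
    "ttp_mean", "ttp_sd", "mpe", "hotspot"))
  het <- as.vector(vapply(c("quick", "intermediate", "slow"), function(cl) {
    c(paste0("kin_het_", cl, "_",
             c("wis_mean", "wis_sd", "wos_mean", "wos_sd",
               "pe_mean", "pe_sd")),
      paste0("kin_het_", cl, "_prop"))
  }, character(7)))
  tex <- as.vector(vapply(c("wis", "wos", "pe"), function(mp) {
    paste0("kin_tex_", mp, "_",
           c("asm", "contrast", "correlation", "variance", "idm",
             "sum_average", "sum_variance", "sum_entropy", "entropy",
             "difference_variance", "difference_entropy", "imc1", "imc2",
             "avd", "hist_mean", "hist_sd", "hist_skewness",
             "hist_kurtosis", "hist_entropy"))
  }, character(19)))
  c(agg, het, tex)
}

#' Cell populations scored by the abundance module
#'
#' The fixed list of 8 immune and 2 stromal populations whose abundance is
#' estimated from marker-gene expression.
#'
#' @return Character vector of 10 population names.
#' @export
cell_populations <- function() {
  c("t_cells", "cd8_t_cells", "cytotoxic_lymphocytes", "nk_cells",
    "b_lineage", "monocytic_lineage", "myeloid_dendritic_cells",
    "neutrophils", "endothelial_cells", "fibroblasts")
}

# family tag for each feature (used to group heatmap rows)
feature_family <- function(names) {
  fam <- rep("texture", length(names))
  fam[startsWith(names, "shape_")] <- "shape"
  fam[startsWith(names, "fo_")] <- "first_order"
  fam[startsWith(names, "kin_")] <- "kinetic"
  fam
}
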