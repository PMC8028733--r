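#' DCE-MRI lesion study container
#'
#' Bundles the four phases of a dynamic contrast-enhanced acquisition (one
#' pre-contrast and three post-contrast volumes), the binary tumor mask, the
#' voxel spacing and the acquisition times into a validated object that every
#' feature extractor consumes.
#'
#' @param phases List of four 3D numeric arrays on a shared grid, ordered
#'   pre-contrast, post-contrast 1..3.
#' @param mask 3D array of 0/1 (or logical) with the same dimensions.
#' @param spacing Numeric length-3 voxel spacing in mm (dim order of the
#'   arrays).
#' @param times Numeric length-4 acquisition times in minutes, strictly
#'   increasing; `times[1]` is the pre-contrast time.
#' @param lesion_id Character scalar identifier.
#' @param institution Character scalar ("A"/"B" for the synthetic profiles).
#' @return An object of class `dce_study`.
#' @export
dce_study <- function(phases, mask, spacing, times = c(0, 1, 2, 3),
                      lesion_id = "lesion", institution = "A") {
  if (!is.list(phases) || length(phases) != 4L)
    stop("`phases` must be a list of 4 volumes (pre + 3 post-contrast)")
  dims <- dim(phases[[1]])
  if (length(dims) != 3L)
    stop("phase volumes must be 3D arrays")
  for (k in seq_along(phases)) {
    if (!identical(dim(phases[[k]]), dims))
      stop("phase ", k, " does not share the grid of phase 1")
  }
  if (!identical(dim(mask), dims))
    stop("`mask` does not share the grid of the phases")
  bad <- setdiff(unique(as.vector(mask)), c(0, 1, FALSE, TRUE))
  if (length(bad))
    stop("`mask` must be binary; found values: ",
         paste(utils::head(bad, 5), collapse = ", "))
  mask <- array(as.integer(mask != 0), dims)
  if (sum(mask) < 1L) stop("`mask` is empty: no in-mask voxel")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive mm values")
  if (length(times) != 4L || any(diff(times) <= 0))
    stop("`times` must be 4 strictly increasing minutes")
  structure(list(phases = phases, mask = mask,
                 spacing = as.numeric(spacing), times = as.numeric(times),
                 lesion_id = as.character(lesion_id),
                 institution = as.character(institution)),
            class = "dce_study")
}

#' @export
print.dce_study <- function(x, ...) {
  cat("<dce_study> ", x$lesion_id, " [institution ", x$institution, "]\n",
      "  grid ", paste(dim(x$mask), collapse = "x"),
      ", spacing ", paste(signif(x$spacing, 3), collapse = "x"), " mm\n",
      "  times ", paste(x$times, collapse = ", "), " min; ",
      sum(x$mask), " mask voxels\n", sep = "")
  invisible(x)
}

#' Read a DCE study from NIfTI files
#'
#' @param phase_paths Character vector of 4 NIfTI paths (pre, post1..post3).
#' @param mask_path NIfTI path of the binary tumor mask.
#' @param times Acquisition times in minutes.
#' @param lesion_id,institution Metadata passed through to [dce_study()].
#' @return A `dce_study`.
#' @export
read_study <- function(phase_paths, mask_path, times = c(0, 1, 2, 3),
                       lesion_id = "lesion", institution = "A") {
  if (length(phase_paths) != 4L)
    stop("need 4 phase paths (pre + 3 post-contrast)")
  missing <- c(phase_paths, mask_path)[!file.exists(c(phase_paths, mask_path))]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  phases <- lapply(phase_paths, function(p) {
    img <- RNifti::readNifti(p)
    array(as.numeric(img), dim(img))
  })
  mimg <- RNifti::readNifti(mask_path)
  mask <- array(as.numeric(mimg), dim(mimg))
  spacing <- RNifti::pixdim(mimg)[seq_len(3)]
  dce_study(phases, mask, spacing, times, lesion_id, institution)
}

#' Write a DCE study as NIfTI files
#'
#' Writes one file per phase (`<prefix>_phase0.nii.gz` ... `_phase3.nii.gz`)
#' plus `<prefix>_mask.nii.gz`.
#'
#' @param study A `dce_study`.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of written paths.
#' @export
write_study <- function(study, prefix) {
  stopifnot(inherits(study, "dce_study"))
  paths <- c(sprintf("%s_phase%d.nii.gz", prefix, 0:3),
             sprintf("%s_mask.nii.gz", prefix))
  put <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- study$spacing
    RNifti::writeNifti(img, path)
  }
  for (k in 1:4) put(study$phases[[k]], paths[k])
  put(study$mask, paths[5])
  invisible(paths)
}

# Crop all volumes to the mask bounding box (texture/shape code works on the
# cropped grid; features are unaffected because out-of-mask voxels are ignored).
crop_to_mask <- function(study, pad = 0L) {
  idx <- which(study$mask == 1L, arr.ind = TRUE)
  rng <- lapply(1:3, function(d) {
    lo <- max(1L, min(idx[, d]) - pad)
    hi <- min(dim(study$mask)[d], max(idx[, d]) + pad)
    lo:hi
  })
  study$phases <- lapply(study$phases,
                         function(p) p[rng[[1]], rng[[2]], rng[[3]], drop = FALSE])
  study$mask <- study$mask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  study
}
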