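#' Synthetic cohort configuration
#'
#' Describes a paired imaging + expression cohort with known ground truth.
#' Lesions are ellipsoidal phantoms whose in-mask voxels follow one of three
#' enhancement archetypes (quick / intermediate / slow time-to-peak), with
#' piecewise-linear curves so that every semi-quantitative kinetic parameter
#' has a closed form. Two institution profiles emulate differing acquisition
#' geometry: profile "A" is axial-like (finer in-plane grid, 2 mm slices),
#' profile "B" sagittal-like (coarser grid, 2.2 mm slices) with a fixed
#' affine intensity shift, inducing a recoverable batch structure.
#'
#' @param n_lesions Number of lesions/samples (>= 2).
#' @param institution_profile `"A"` or `"B"`; fills geometry defaults.
#' @param grid_shape Integer length-3 (Z, Y, X) voxel grid.
#' @param voxel_spacing Numeric length-3 mm.
#' @param acquisition_times Length-4 minutes, strictly increasing;
#'   `[1]` is the pre-contrast time.
#' @param ttp_fractions Simplex triple (quick, intermediate, slow) of
#'   expected archetype proportions.
#' @param archetype_params Per-archetype list with `peak_level` (relative
#'   enhancement at peak), `peak_phase` (1..3) and `washout` (enhancement
#'   units/min decline after the peak).
#' @param noise_sd Gaussian intensity noise SD (baseline signal is 100).
#' @param expr_noise_sd SD of the log2-scale noise on marker-gene expression.
#' @param planted_assoc List of `list(feature, population, r)` entries:
#'   target Pearson correlation in `[-1, 1]` between the named radiomic
#'   feature and the population's true abundance, realized through a shared
#'   latent amplitude variable (Gaussian copula).
#' @param n_genes Total gene count of the expression matrix.
#' @param markers_per_pop Marker genes per population.
#' @param seed Integer seed; mandatory for determinism.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_lesions,
                          institution_profile = c("A", "B"),
                          grid_shape = NULL,
                          voxel_spacing = NULL,
                          acquisition_times = c(0, 1, 2, 3),
                          ttp_fractions = c(0.4, 0.3, 0.3),
                          archetype_params = default_archetypes(),
                          noise_sd = 2,
                          expr_noise_sd = 0.25,
                          planted_assoc = list(),
                          n_genes = 2000L,
                          markers_per_pop = 5L,
                          seed = 1L) {
  institution_profile <- match.arg(institution_profile)
  prof <- institution_profiles()[[institution_profile]]
  if (is.null(grid_shape)) grid_shape <- prof$grid_shape
  if (is.null(voxel_spacing)) voxel_spacing <- prof$voxel_spacing
  if (n_lesions < 2) stop("`n_lesions` must be >= 2")
  if (abs(sum(ttp_fractions) - 1) > 1e-12)
    stop("`ttp_fractions` must sum to 1")
  if (any(ttp_fractions < 0)) stop("`ttp_fractions` must be non-negative")
  if (length(acquisition_times) != 4L || any(diff(acquisition_times) <= 0))
    stop("`acquisition_times` must be 4 strictly increasing minutes")
  for (pa in planted_assoc) {
    if (!pa$feature %in% feature_catalog())
      stop("planted feature '", pa$feature, "' is not in the 199-feature ",
           "catalog; valid names: see feature_catalog()")
    if (!pa$population %in% cell_populations())
      stop("planted population '", pa$population, "' unknown")
    if (abs(pa$r) > 1) stop("planted correlation must be in [-1, 1]")
  }
  structure(list(n_lesions = as.integer(n_lesions),
                 institution_profile = institution_profile,
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 acquisition_times = as.numeric(acquisition_times),
                 ttp_fractions = as.numeric(ttp_fractions),
                 archetype_params = archetype_params,
                 noise_sd = noise_sd, expr_noise_sd = expr_noise_sd,
                 planted_assoc = planted_assoc,
                 n_genes = as.integer(n_genes),
                 markers_per_pop = as.integer(markers_per_pop),
                 seed = as.integer(seed),
                 intensity_affine = prof$intensity_affine),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_archetypes <- function() {
  list(quick = list(peak_level = 1.2, peak_phase = 1L, washout = 0.25),
       intermediate = list(peak_level = 1.0, peak_phase = 2L, washout = 0.15),
       slow = list(peak_level = 0.85, peak_phase = 3L, washout = 0))
}

# desk-scale stand-ins for the axial 512x512/2 mm and sagittal 256x256/2.2 mm
# acquisition geometries; profile B additionally applies a fixed intensity
# affine shift so cross-institution batch structure is recoverable
institution_profiles <- function() {
  list(A = list(grid_shape = c(14L, 32L, 32L),
                voxel_spacing = c(2.0, 0.7, 0.7),
                intensity_affine = c(scale = 1, shift = 0)),
       B = list(grid_shape = c(14L, 24L, 24L),
                voxel_spacing = c(2.2, 0.9, 0.9),
                intensity_affine = c(scale = 1.12, shift = 18)))
}

#' Generate one synthetic lesion study
#'
#' Draws a random-axis ellipsoid mask, assigns each in-mask voxel an
#' enhancement archetype (multinomially, matching `ttp_fractions` in
#' expectation), and builds the 4-phase signal: a piecewise-linear rise from
#' baseline 100 to the archetype's (amplitude-scaled) peak, a linear washout
#' after it, plus Gaussian noise of SD `noise_sd`, then the institution's
#' affine intensity map.
#'
#' @param config A [cohort_config()].
#' @param lesion_index 1-based lesion index (enters the per-lesion seed).
#' @param amp Amplitude multiplier applied to all archetype peak levels
#'   (the coupling handle used by [gen_cohort()] to plant correlations).
#' @return List with `study` (a [dce_study()]) and `truth` (list with the
#'   per-voxel `archetype` label array and `amp`).
#' @export
gen_lesion_study <- function(config, lesion_index, amp = 1) {
  stopifnot(inherits(config, "cohort_config"))
  d <- config$grid_shape
  withr::with_seed(config$seed + 7919L * as.integer(lesion_index), {
    ctr <- d / 2 + stats::runif(3, -1, 1)
    semi <- c(stats::runif(1, 0.16, 0.30) * d[1],
              stats::runif(1, 0.16, 0.30) * d[2],
              stats::runif(1, 0.16, 0.30) * d[3])
    co <- arrayInd(seq_len(prod(d)), d)
    inside <- ((co[, 1] - ctr[1]) / semi[1])^2 +
      ((co[, 2] - ctr[2]) / semi[2])^2 +
      ((co[, 3] - ctr[3]) / semi[3])^2 <= 1
    if (sum(inside) < 30)
      stop("grid_shape ", paste(d, collapse = "x"),
           " too small for an ellipsoid mask of >= 30 voxels")
    mask <- array(as.integer(inside), d)
    nvox <- sum(inside)
    arch <- sample(c("quick", "intermediate", "slow"), nvox,
                   replace = TRUE, prob = config$ttp_fractions)
    labels <- array(NA_character_, d)
    labels[inside] <- arch
    times <- config$acquisition_times
    base <- 100
    phases <- lapply(1:4, function(k) array(base, d))
    for (a in c("quick", "intermediate", "slow")) {
      ap <- config$archetype_params[[a]]
      sel <- inside & as.vector(labels == a & !is.na(labels))
      if (!any(sel)) next
      pk <- ap$peak_level * amp
      tpk <- times[ap$peak_phase + 1L]
      for (k in 2:4) {
        tk <- times[k]
        e <- if (tk <= tpk) pk * (tk - times[1]) / (tpk - times[1])
             else pk - ap$washout * (tk - tpk)
        phases[[k]][sel] <- base * (1 + e)
      }
    }
    if (config$noise_sd > 0)
      phases <- lapply(phases, function(p)
        p + array(stats::rnorm(prod(d), 0, config$noise_sd), d))
    aff <- config$intensity_affine
    phases <- lapply(phases, function(p) aff[["scale"]] * p + aff[["shift"]])
    study <- dce_study(phases, mask, config$voxel_spacing, times,
                       lesion_id = sprintf("%s%03d",
                                           config$institution_profile,
                                           lesion_index),
                       institution = config$institution_profile)
    list(study = study, truth = list(archetype = labels, amp = amp))
  })
}

#' Default synthetic marker sets
#'
#' A marker table (population, gene) with `markers_per_pop` synthetic marker
#' genes per population, matching the genes emitted by [gen_expression()].
#' Real marker lists (e.g. MCP-counter's) can be substituted by loading any
#' two-column table with [read_markers()].
#'
#' @param markers_per_pop Markers per population (default 5).
#' @return Named list: population -> character vector of marker gene IDs.
#' @export
default_marker_sets <- function(markers_per_pop = 5L) {
  pops <- cell_populations()
  stats::setNames(lapply(pops, function(p)
    sprintf("%s_m%d", p, seq_len(markers_per_pop))), pops)
}

#' Generate a synthetic expression matrix
#'
#' Marker genes of population k are log-normal with log2-scale location
#' shifted by the sample's true abundance (`log2(1 + count) =
#' mu_gene + slope * abundance + noise`, slope 1); the remaining genes are
#' abundance-independent background. The matrix is genes x samples and
#' non-negative.
#'
#' @param config A [cohort_config()].
#' @param truth Cohort ground truth with `abundance` (samples x 10 matrix).
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
gen_expression <- function(config, truth) {
  stopifnot(inherits(config, "cohort_config"))
  ab <- truth$abundance
  n <- nrow(ab)
  markers <- default_marker_sets(config$markers_per_pop)
  ov <- unlist(markers)[duplicated(unlist(markers))]
  if (length(ov)) warning("marker sets overlap across populations: ",
                          paste(unique(ov), collapse = ", "))
  marker_genes <- unlist(markers, use.names = FALSE)
  n_bg <- config$n_genes - length(marker_genes)
  if (n_bg < 0) stop("`n_genes` smaller than the total marker count")
  genes <- c(marker_genes, sprintf("bg_%04d", seq_len(n_bg)))
  withr::with_seed(config$seed + 104729L, {
    mu <- stats::runif(length(genes), 4, 8)
    x <- matrix(mu, length(genes), n)           # log2(1 + count)
    for (p in seq_along(markers)) {
      gi <- match(markers[[p]], genes)
      x[gi, ] <- x[gi, ] + rep(ab[, p], each = length(gi))
    }
    if (config$expr_noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), 0, config$expr_noise_sd),
                      nrow(x), ncol(x))
    counts <- pmax(2^x - 1, 0)
    dimnames(counts) <- list(genes, rownames(ab))
    counts
  })
}

#' Generate a paired imaging + expression cohort
#'
#' Draws a shared latent amplitude variable per lesion; planted
#' `(feature, population, r)` entries couple the population's true abundance
#' to that latent via a Gaussian copula, so the abundance correlates with
#' amplitude-driven radiomic features (mean PE, MPE, hot spot, ...) at
#' approximately the target `r`. The correlation actually realized between
#' the amplitude and each planted abundance is recorded in the ground truth.
#'
#' @param config A [cohort_config()].
#' @return List with `studies` (list of [dce_study()]), `expression`
#'   (genes x samples matrix), and `truth` (per-lesion archetype labels,
#'   samples x 10 `abundance` matrix, `amp` vector, and `realized_r` for
#'   each planted association).
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_lesions
  pops <- cell_populations()
  sample_ids <- sprintf("%s%03d", config$institution_profile, seq_len(n))
  withr::with_seed(config$seed, {
    u <- stats::rnorm(n)                        # shared latent amplitude
    amp <- pmax(1 + 0.25 * u, 0.2)
    ab <- matrix(stats::rnorm(n * 10, mean = 3, sd = 1), n, 10,
                 dimnames = list(sample_ids, pops))
    for (pa in config$planted_assoc) {
      z <- pa$r * u + sqrt(1 - pa$r^2) * stats::rnorm(n)
      ab[, pa$population] <- 3 + z
    }
  })
  lesions <- lapply(seq_len(n), function(i)
    gen_lesion_study(config, i, amp = amp[i]))
  studies <- lapply(lesions, `[[`, "study")
  truth <- list(
    archetype = lapply(lesions, function(l) l$truth$archetype),
    abundance = ab, amp = amp,
    realized_r = vapply(config$planted_assoc, function(pa)
      stats::cor(amp, ab[, pa$population]), numeric(1)))
  expr <- gen_expression(config, truth)
  list(studies = studies, expression = expr, truth = truth)
}
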