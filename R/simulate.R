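#' Synthetic n-alkane calibration ladder
#'
#' Emulates a C8--C40 linear-alkane standard mixture on a
#' temperature-programmed GC run: retention time grows affinely in carbon
#' number with optional mild quadratic curvature and seeded jitter, while
#' remaining strictly monotone.
#'
#' @param carbons carbon numbers (default 8:40).
#' @param rt_start retention time of the first alkane (min).
#' @param spacing mean retention-time spacing per carbon (min).
#' @param curvature quadratic curvature coefficient (min per carbon^2).
#' @param jitter_sd SD of seeded retention-time jitter (min); kept small
#'   relative to spacing so monotonicity is preserved.
#' @param seed RNG seed (required when `jitter_sd > 0`).
#' @return An [alkane_ladder()].
#' @export
gen_alkane_ladder <- function(carbons = 8:40, rt_start = 5, spacing = 1.2,
                              curvature = 0, jitter_sd = 0, seed = NULL) {
  d <- carbons - carbons[1]
  rt <- rt_start + spacing * d + curvature * d^2
  if (jitter_sd > 0) {
    if (is.null(seed)) stop("a seed is required for jittered output")
    withr_seed(seed)
    jit <- stats::rnorm(length(rt), 0, jitter_sd)
    rt <- rt + jit
    rt <- cummax(rt + seq_along(rt) * 1e-9)  # enforce strict monotonicity
  }
  alkane_ladder(carbons, rt)
}

# local seeded evaluation without touching the global RNG stream permanently
withr_seed <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
}

#' Synthetic EI spectrum of a saturated alkane
#'
#' Produces the alkyl fragment ladder at m/z = 14 n + 1 up to the parent
#' mass minus 15, with intensities following `A exp(-lambda m)` under
#' multiplicative lognormal noise; the diagnostic ions of every methyl
#' branch are multiplied by the enhancement factor, and a weak parent ion is
#' placed at the nominal mass.
#'
#' @param structure a saturated [hydrocarbon()].
#' @param A decay amplitude (default 1000).
#' @param lambda decay rate per Da (default 0.02).
#' @param enhancement multiplicative boost of diagnostic ions (default 5).
#' @param noise_sigma lognormal sigma of multiplicative intensity noise
#'   (default 0: noiseless).
#' @param parent_intensity_frac parent-ion intensity as a fraction of the
#'   envelope at the parent mass (default 0.5).
#' @param seed RNG seed (required when `noise_sigma > 0`).
#' @return An [ei_spectrum()] with `parent_mass` and ground-truth attributes
#'   `truth` (the structure) and `enhanced_mz`.
#' @export
gen_ei_spectrum <- function(structure, A = 1000, lambda = 0.02,
                            enhancement = 5, noise_sigma = 0,
                            parent_intensity_frac = 0.5, seed = NULL) {
  stopifnot(inherits(structure, "hydrocarbon"))
  if (!is.null(structure$other_class) || structure$n_double_bonds > 0L) {
    stop("spectrum generation is defined for saturated alkanes only")
  }
  M <- nominal_mass(formula_of(structure))
  n <- 3:((M - 15 - 1) %/% 14)
  mz <- 14 * n + 1
  intensity <- A * exp(-lambda * mz)
  diag_mz <- diagnostic_ions(structure)
  intensity[mz %in% diag_mz] <- intensity[mz %in% diag_mz] * enhancement
  if (noise_sigma > 0) {
    if (is.null(seed)) stop("a seed is required for noisy output")
    withr_seed(seed)
    intensity <- intensity * exp(stats::rnorm(length(intensity), 0,
                                              noise_sigma))
  }
  mz <- c(mz, M)
  intensity <- c(intensity, parent_intensity_frac * A * exp(-lambda * M))
  out <- ei_spectrum(mz, intensity, parent_mass = M)
  attr(out, "truth") <- structure
  attr(out, "enhanced_mz") <- diag_mz
  out
}

#' Synthetic chromatogram cohort (trophallactic fluid vs body, per colony)
#'
#' Emulates the five-colony design: a species-wide pool of Gaussian peaks in
#' the long-chain hydrocarbon window, from which each sample realizes a
#' subset. Trophallactic-fluid samples share a larger fraction of the
#' species pool across colonies than body samples, whose composition is
#' dominated by colony-specific subsets -- the effect under study. Peak
#' heights get per-sample lognormal variation and the trace carries additive
#' Gaussian baseline noise.
#'
#' @param n_colonies number of colonies (default 5).
#' @param n_peaks size of the species-wide peak pool (default 25).
#' @param window retention-time window in minutes (default 36--51).
#' @param peak_sd Gaussian peak width in minutes (default 0.02).
#' @param tf_share fraction of the pool every TF sample carries
#'   (default 0.9).
#' @param body_share fraction of the pool every body sample carries
#'   (default 0.5); the retained subset is drawn per colony, making body
#'   profiles colony-specific.
#' @param height_sigma lognormal sigma of per-sample peak-height variation
#'   (default 0.3).
#' @param noise_sd additive baseline noise SD, relative to unit peak height
#'   (default 0.01).
#' @param dt trace sampling interval in minutes (default 0.01).
#' @param seed RNG seed (required).
#' @return A list with `chromatograms` (named list of [chromatogram()]),
#'   `meta` (sample_id, colony, source), and `truth` (per-sample peak
#'   positions and heights).
#' @export
gen_cohort <- function(n_colonies = 5, n_peaks = 25, window = c(36, 51),
                       peak_sd = 0.02, tf_share = 0.9, body_share = 0.5,
                       height_sigma = 0.3, noise_sd = 0.01, dt = 0.01,
                       seed = NULL) {
  if (is.null(seed)) stop("a seed is required")
  stopifnot(tf_share >= 0, tf_share <= 1, body_share >= 0, body_share <= 1)
  withr_seed(seed)
  rt_grid <- seq(window[1], window[2], by = dt)
  # species-wide pool: positions kept >= 5 peak SDs apart, stable heights
  pool_rt <- sort(stats::runif(n_peaks, window[1] + 0.5, window[2] - 0.5))
  while (any(diff(pool_rt) < 5 * peak_sd)) {
    pool_rt <- sort(stats::runif(n_peaks, window[1] + 0.5, window[2] - 0.5))
  }
  pool_height <- exp(stats::rnorm(n_peaks, 0, 0.5))
  colonies <- paste0("C", 10 + seq_len(n_colonies))
  chroms <- list()
  meta <- NULL
  truth <- NULL
  for (cy in colonies) {
    body_keep <- sort(sample.int(n_peaks, max(2L, round(body_share *
                                                          n_peaks))))
    for (src in c("TF", "body")) {
      keep <- if (src == "TF") {
        sort(sample.int(n_peaks, max(2L, round(tf_share * n_peaks))))
      } else {
        body_keep
      }
      h <- pool_height[keep] * exp(stats::rnorm(length(keep), 0,
                                                height_sigma))
      y <- numeric(length(rt_grid))
      for (i in seq_along(keep)) {
        y <- y + h[i] * exp(-(rt_grid - pool_rt[keep[i]])^2 /
                              (2 * peak_sd^2))
      }
      y <- y + stats::rnorm(length(y), 0, noise_sd)
      y <- pmax(y, 0)
      id <- paste0(cy, "_", src)
      chroms[[id]] <- chromatogram(rt_grid, y, sample_id = id, colony = cy,
                                   source = src)
      meta <- rbind(meta, data.frame(sample_id = id, colony = cy,
                                     source = src))
      truth <- rbind(truth, data.frame(sample_id = id,
                                       peak_rt = pool_rt[keep],
                                       height = h))
    }
  }
  list(chromatograms = chroms, meta = meta, truth = truth)
}

#' Synthetic spectral-count matrix with condition effects
#'
#' Counts are drawn from a negative binomial whose mean is proportional to
#' protein length times a per-protein abundance factor; a configured
#' fraction of proteins carries a multiplicative effect in the second
#' condition. Ground-truth flags are returned with the matrix.
#'
#' @param n_proteins number of proteins (default 40).
#' @param n_per_condition samples per condition (default 6).
#' @param length_range protein length range in residues (default 100--1000).
#' @param base_rate expected counts per residue at abundance 1
#'   (default 0.05).
#' @param abundance_sigma lognormal sigma of per-protein abundance
#'   (default 1).
#' @param dispersion negative-binomial size parameter (default 5).
#' @param effect multiplicative condition effect (1 = null; default 1).
#' @param affected_fraction fraction of proteins carrying the effect
#'   (default 0).
#' @param conditions condition labels (default in-colony / isolated).
#' @param seed RNG seed (required).
#' @return A list with `matrix` (an [spc_matrix()]) and `truth` (per-protein
#'   logical effect flags).
#' @export
gen_count_matrix <- function(n_proteins = 40, n_per_condition = 6,
                             length_range = c(100, 1000), base_rate = 0.05,
                             abundance_sigma = 1, dispersion = 5,
                             effect = 1, affected_fraction = 0,
                             conditions = c("in-colony", "isolated"),
                             seed = NULL) {
  if (is.null(seed)) stop("a seed is required")
  withr_seed(seed)
  lens <- round(stats::runif(n_proteins, length_range[1], length_range[2]))
  abund <- exp(stats::rnorm(n_proteins, 0, abundance_sigma))
  n_aff <- round(affected_fraction * n_proteins)
  affected <- rep(FALSE, n_proteins)
  if (n_aff > 0) affected[sample.int(n_proteins, n_aff)] <- TRUE
  n_s <- 2 * n_per_condition
  cond <- rep(conditions, each = n_per_condition)
  colony <- rep(paste0("C", seq_len(n_per_condition)), times = 2)
  mu <- matrix(base_rate * lens * abund, n_proteins, n_s)
  mu[affected, cond == conditions[2]] <-
    mu[affected, cond == conditions[2]] * effect
  counts <- matrix(stats::rnbinom(n_proteins * n_s, mu = mu,
                                  size = dispersion),
                   n_proteins, n_s)
  # guard the all-zero-column invariant for tiny configurations
  for (j in which(colSums(counts) == 0)) counts[1, j] <- 1L
  rownames(counts) <- sprintf("P%03d", seq_len(n_proteins))
  colnames(counts) <- paste0("S", seq_len(n_s), "_",
                             ifelse(cond == conditions[1], "a", "b"))
  meta <- data.frame(sample_id = colnames(counts), condition = cond,
                     colony = colony)
  list(matrix = spc_matrix(counts, lens, meta),
       truth = data.frame(protein = rownames(counts), affected = affected))
}
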