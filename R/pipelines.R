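#' Elucidation pipeline over a directory of spectra
#'
#' Runs [identify_compound()] on every spectrum CSV in a directory and
#' assembles an annotated compound table (one row per spectrum) with the
#' columns of the reference compound table: retention time, nominal mass,
#' proposed formula, proposed structure and retention index, plus flags.
#' Per-spectrum failures are collected into the `flags` column; the run
#' continues.
#'
#' @param spectra_dir directory of spectrum CSVs (columns `mz`, `intensity`,
#'   optional `parent_mass`, `rt_min`).
#' @param ladder an [alkane_ladder()] or path to a ladder CSV.
#' @param ri_reference optional [build_ri_curves()] input (data frame or
#'   CSV path).
#' @param out optional output CSV path.
#' @param tau,pair_tol,ri_tol,max_fit_iterations elucidation settings, see
#'   [identify_compound()].
#' @return The compound table (data frame), invisibly written to `out` when
#'   given.
#' @export
run_elucidate <- function(spectra_dir, ladder, ri_reference = NULL,
                          out = NULL, tau = 3, pair_tol = 1, ri_tol = 15,
                          max_fit_iterations = 5L) {
  if (is.character(ladder)) ladder <- read_ladder_csv(ladder)
  curves <- NULL
  if (!is.null(ri_reference)) {
    if (is.character(ri_reference)) {
      ri_reference <- read_ri_reference_csv(ri_reference)
    }
    curves <- build_ri_curves(ri_reference)
  }
  files <- sort(list.files(spectra_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  rows <- lapply(files, function(f) {
    row <- data.frame(file = basename(f), rt_min = NA_real_, mw = NA_integer_,
                      proposed_mf = NA_character_,
                      proposed_structure = NA_character_, ri = NA_integer_,
                      flags = "")
    spec <- tryCatch(read_spectrum_csv(f), error = function(e) e)
    if (inherits(spec, "error")) {
      row$flags <- paste("parse error:", conditionMessage(spec))
      return(row)
    }
    res <- tryCatch(
      identify_compound(spec, ladder = ladder, curves = curves, tau = tau,
                        pair_tol = pair_tol, ri_tol = ri_tol,
                        max_fit_iterations = max_fit_iterations),
      error = function(e) e)
    if (inherits(res, "error")) {
      row$flags <- conditionMessage(res)
      return(row)
    }
    row$rt_min <- if (!is.null(spec$rt)) spec$rt else NA_real_
    row$mw <- spec$parent_mass
    if (res$inconclusive) {
      row$flags <- res$reason
      return(row)
    }
    if (length(res$candidates)) {
      best <- res$candidates[[1]]
      row$proposed_mf <- format(formula_of(best))
      row$proposed_structure <- if (length(res$candidates) > 1L) {
        amb <- best; amb$ambiguous <- TRUE
        format(amb)
      } else {
        format(best)
      }
      if (!is.null(res$ri_check)) {
        verdicts <- vapply(res$ri_check, `[[`, character(1), "verdict")
        if (!any(verdicts == "pass")) {
          row$flags <- paste0("RI check: ", paste(unique(verdicts),
                                                  collapse = "/"))
        }
      }
    } else {
      row$flags <- "no structure consistent with enhanced ions"
    }
    if (!is.na(res$ri)) row$ri <- ri_round(res$ri)
    row
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0), rt_min = numeric(0), mw = integer(0),
               proposed_mf = character(0), proposed_structure = character(0),
               ri = integer(0), flags = character(0))
  if (!is.null(out)) utils::write.csv(tab, out, row.names = FALSE)
  tab
}

#' Profile-comparison pipeline
#'
#' Normalizes every chromatogram of a cohort, detects and bins peaks,
#' computes the pairwise cross-correlation similarity matrix, tests whether
#' trophallactic-fluid profiles are more similar across colonies than body
#' profiles, and clusters the binned profiles with bootstrap support.
#'
#' @param cohort a manifest CSV path, or a list with `chromatograms` and
#'   `meta` (as produced by [gen_cohort()] or [read_cohort_manifest()]).
#' @param window retention-time window (min).
#' @param rel_threshold peak detection threshold on the normalized trace.
#' @param bin_width bin width in minutes.
#' @param max_lag cross-correlation lag search radius in bins.
#' @param n_boot bootstrap replicates for clustering.
#' @param test_method group-comparison method, see [compare_groups()].
#' @param seed RNG seed for the bootstrap.
#' @param out_dir optional output directory (similarity CSV, test JSON,
#'   dendrogram Newick).
#' @return A list with `similarity`, `pairs`, `test`, `clustering`,
#'   `profiles`.
#' @export
run_profile_compare <- function(cohort, window = c(36, 51),
                                rel_threshold = 0.07, bin_width = 0.03,
                                max_lag = 0L, n_boot = 1000L,
                                test_method = "welch", seed = 1L,
                                out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort_manifest(cohort)
  meta <- cohort$meta
  if (length(unique(meta$colony)) < 2L) {
    stop("need at least two colonies for cross-colony comparison")
  }
  profiles <- lapply(cohort$chromatograms, function(ch) {
    bin_peaks(find_peaks(normalize_profile(ch, window), rel_threshold),
              bin_width = bin_width, window = window)
  })
  sim <- similarity_matrix(profiles, meta, max_lag = max_lag)
  pairs <- similarity_pairs(sim)
  test <- compare_groups(pairs, method = test_method)
  withr_seed(seed)
  mat <- do.call(cbind, lapply(profiles, as.numeric))
  colnames(mat) <- names(profiles)
  clustering <- hierarchical_cluster(mat, n_boot = n_boot)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(unclass(sim)),
                     file.path(out_dir, "similarity_matrix.csv"))
    jsonlite::write_json(
      list(test = test, seed = seed, n_boot = n_boot,
           settings = list(window = window, rel_threshold = rel_threshold,
                           bin_width = bin_width, max_lag = max_lag)),
      file.path(out_dir, "test_report.json"), auto_unbox = TRUE, digits = NA)
    write_newick(clustering, file.path(out_dir, "dendrogram.nwk"))
  }
  list(similarity = sim, pairs = pairs, test = test, clustering = clustering,
       profiles = profiles)
}

#' NSAF quantification pipeline
#'
#' Computes NSAF values from a spectral-count matrix, restricts to the most
#' abundant proteins, tests for condition differences with Bonferroni
#' control and clusters the samples.
#'
#' @param counts an [spc_matrix()] or a counts CSV path.
#' @param meta_path metadata CSV path when `counts` is a path.
#' @param top number of most-abundant proteins tested (default 40).
#' @param alpha family-wise level (default 0.05).
#' @param family_size Bonferroni family size override.
#' @param n_boot bootstrap replicates for clustering.
#' @param seed RNG seed for the bootstrap.
#' @param out_dir optional output directory (NSAF CSV, flags CSV, Newick).
#' @return A list with `nsaf`, `relative`, `test`, `clustering`.
#' @export
run_nsaf <- function(counts, meta_path = NULL, top = 40L, alpha = 0.05,
                     family_size = NULL, n_boot = 1000L, seed = 1L,
                     out_dir = NULL) {
  if (is.character(counts)) counts <- read_counts_csv(counts, meta_path)
  stopifnot(inherits(counts, "spc_matrix"))
  values <- nsaf(counts)
  sel <- top_proteins(values, top)
  rel <- relative_nsaf(values, sel)
  test <- NULL
  if (!is.null(counts$meta) && length(unique(counts$meta$condition)) == 2L) {
    test <- condition_test(values[sel, , drop = FALSE],
                           counts$meta$condition, counts$meta$colony,
                           alpha = alpha, family_size = family_size)
  }
  withr_seed(seed)
  clustering <- cluster_samples(values, n_boot = n_boot)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(values),
                     file.path(out_dir, "nsaf.csv"))
    if (!is.null(test)) {
      utils::write.csv(test, file.path(out_dir, "condition_flags.csv"),
                       row.names = FALSE)
    }
    write_newick(clustering, file.path(out_dir, "dendrogram.nwk"))
  }
  list(nsaf = values, relative = rel, test = test, clustering = clustering)
}

#' Generate a synthetic scenario to disk
#'
#' Writes one of the synthetic input classes (`ladder`, `spectrum`,
#' `cohort`, `counts`) in the same CSV dialects the analysis functions read,
#' together with its ground-truth tables.
#'
#' @param scenario one of `"ladder"`, `"spectrum"`, `"cohort"`, `"counts"`.
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @param ... passed to the matching generator.
#' @return The output directory, invisibly.
#' @export
run_generate <- function(scenario = c("ladder", "spectrum", "cohort",
                                      "counts"),
                         out_dir, seed = 1L, ...) {
  scenario <- match.arg(scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(scenario,
    ladder = {
      lad <- gen_alkane_ladder(seed = seed, ...)
      write_ladder_csv(lad, file.path(out_dir, "ladder.csv"))
    },
    spectrum = {
      args <- list(...)
      if (is.null(args$structure)) args$structure <- hydrocarbon(29, 9)
      args$seed <- seed
      spec <- do.call(gen_ei_spectrum, args)
      write_spectrum_csv(spec, file.path(out_dir, "spectrum.csv"))
      writeLines(format(attr(spec, "truth")),
                 file.path(out_dir, "spectrum_truth.txt"))
    },
    cohort = {
      coh <- gen_cohort(seed = seed, ...)
      paths <- vapply(names(coh$chromatograms), function(id) {
        p <- paste0(id, ".csv")
        write_chromatogram_csv(coh$chromatograms[[id]],
                               file.path(out_dir, p))
        p
      }, character(1))
      manifest <- cbind(coh$meta, path = paths)
      utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                       row.names = FALSE)
      utils::write.csv(coh$truth, file.path(out_dir, "truth_peaks.csv"),
                       row.names = FALSE)
    },
    counts = {
      cm <- gen_count_matrix(seed = seed, ...)
      write_counts_csv(cm$matrix, file.path(out_dir, "counts.csv"),
                       file.path(out_dir, "metadata.csv"))
      utils::write.csv(cm$truth, file.path(out_dir, "truth_flags.csv"),
                       row.names = FALSE)
    })
  invisible(out_dir)
}
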