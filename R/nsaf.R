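#' Spectral-count matrix
#'
#' Container for shotgun-proteomics spectral counts: proteins x samples
#' integer counts, per-protein lengths (residues) and per-sample metadata
#' (condition and colony).
#'
#' @param counts proteins x samples matrix of non-negative integer spectral
#'   counts (rownames = protein ids, colnames = sample ids).
#' @param lengths protein lengths in residues, parallel to the rows.
#' @param meta data frame with columns `sample_id`, `condition`, `colony`
#'   (optional; required for condition testing).
#' @return An object of class `spc_matrix`.
#' @export
spc_matrix <- function(counts, lengths, meta = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("spectral counts must be non-negative integers")
  }
  if (length(lengths) != nrow(counts)) {
    stop("one protein length per row is required")
  }
  if (any(lengths <= 0)) stop("protein lengths must be positive")
  zero_col <- colSums(counts) == 0
  if (any(zero_col)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero_col], collapse = ", "))
  }
  if (!is.null(meta)) {
    need <- c("sample_id", "condition")
    if (!all(need %in% names(meta))) {
      stop("metadata needs columns: ", paste(need, collapse = ", "))
    }
    if (!all(colnames(counts) %in% meta$sample_id)) {
      stop("metadata is missing sample(s): ",
           paste(setdiff(colnames(counts), meta$sample_id), collapse = ", "))
    }
    meta <- meta[match(colnames(counts), meta$sample_id), ]
  }
  structure(list(counts = counts, lengths = as.numeric(lengths),
                 meta = meta),
            class = "spc_matrix")
}

#' @export
print.spc_matrix <- function(x, ...) {
  cat(sprintf("<spectral counts> %d proteins x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$meta)) {
    cat("  conditions:", paste(unique(x$meta$condition), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Normalized spectral abundance factor
#'
#' `NSAF[p, s] = (SpC[p, s] / L[p]) / sum_q (SpC[q, s] / L[q])`: counts are
#' divided by protein length and renormalized within each sample, so every
#' sample column sums to 1. No pseudocounts are added; zero counts give
#' NSAF 0.
#'
#' @param x an [spc_matrix()].
#' @return A proteins x samples matrix of NSAF values.
#' @export
nsaf <- function(x) {
  stopifnot(inherits(x, "spc_matrix"))
  saf <- sweep(x$counts, 1, x$lengths, "/")
  sweep(saf, 2, colSums(saf), "/")
}

#' Rescale NSAF values within a protein subset
#'
#' When reporting only a subset of proteins (e.g. the displayed most
#' abundant ones), each protein's NSAF is divided by the subset's per-sample
#' NSAF total so the displayed values again sum to 1 within each sample.
#'
#' @param nsaf_values matrix from [nsaf()].
#' @param subset protein ids (rownames) or row indices.
#' @return The rescaled subset matrix.
#' @export
relative_nsaf <- function(nsaf_values, subset) {
  sub <- nsaf_values[subset, , drop = FALSE]
  tot <- colSums(sub)
  if (any(tot == 0)) {
    stop("subset has zero NSAF total in sample(s): ",
         paste(colnames(sub)[tot == 0], collapse = ", "))
  }
  sweep(sub, 2, tot, "/")
}

#' Select the most abundant proteins by mean NSAF
#'
#' @param nsaf_values matrix from [nsaf()].
#' @param n number of proteins to keep (default 40).
#' @return Character vector of protein ids, in decreasing mean abundance.
#' @export
top_proteins <- function(nsaf_values, n = 40L) {
  mn <- rowMeans(nsaf_values)
  rownames(nsaf_values)[order(-mn)][seq_len(min(n, nrow(nsaf_values)))]
}

#' Per-protein condition test with Bonferroni control
#'
#' Two-sample t-test per protein on NSAF values between two conditions,
#' paired by colony when every colony has exactly one sample in each
#' condition (the repeated-measures design of sampling the same groups
#' before and after isolation), unpaired otherwise. Proteins with zero
#' variance in both groups are skipped with a warning. A protein is flagged
#' when `p <= alpha / family_size`; the family size defaults to the number
#' of proteins actually tested.
#'
#' @param nsaf_values matrix from [nsaf()] (proteins x samples).
#' @param condition factor/character of per-sample condition labels (two
#'   levels), parallel to the columns.
#' @param colony optional per-sample colony labels enabling pairing.
#' @param alpha family-wise significance level (default 0.05).
#' @param family_size Bonferroni family size; defaults to the number of
#'   proteins tested.
#' @param paired force or forbid pairing; default `NULL` decides from the
#'   colony metadata.
#' @return A data frame with one row per protein: `protein`, `p_value`,
#'   `direction` (sign of condition-2 minus condition-1 mean), `flag`,
#'   `tested`; plus attributes `threshold`, `paired`, `family_size`.
#' @export
condition_test <- function(nsaf_values, condition, colony = NULL,
                           alpha = 0.05, family_size = NULL, paired = NULL) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L) stop("exactly two conditions are required")
  lev <- levels(condition)
  i1 <- which(condition == lev[1]); i2 <- which(condition == lev[2])
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("need at least 2 samples per condition")
  }
  if (is.null(paired)) {
    paired <- !is.null(colony) &&
      length(i1) == length(i2) &&
      !anyDuplicated(colony[i1]) && !anyDuplicated(colony[i2]) &&
      setequal(colony[i1], colony[i2])
  }
  if (paired && !is.null(colony)) {
    i2 <- i2[match(colony[i1], colony[i2])]
  }
  prots <- rownames(nsaf_values)
  if (is.null(prots)) prots <- as.character(seq_len(nrow(nsaf_values)))
  p <- rep(NA_real_, nrow(nsaf_values))
  dirn <- rep(NA_real_, nrow(nsaf_values))
  skipped <- character(0)
  for (r in seq_len(nrow(nsaf_values))) {
    x1 <- nsaf_values[r, i1]; x2 <- nsaf_values[r, i2]
    if (stats::var(x1) == 0 && stats::var(x2) == 0 &&
        (!paired || stats::var(x2 - x1) == 0)) {
      skipped <- c(skipped, prots[r])
      next
    }
    tt <- tryCatch(stats::t.test(x2, x1, paired = paired),
                   error = function(e) NULL)
    if (is.null(tt)) { skipped <- c(skipped, prots[r]); next }
    p[r] <- tt$p.value
    dirn[r] <- sign(mean(x2) - mean(x1))
  }
  if (length(skipped)) {
    warning("skipped protein(s) with zero variance in both groups: ",
            paste(skipped, collapse = ", "))
  }
  tested <- !is.na(p)
  if (is.null(family_size)) family_size <- sum(tested)
  if (family_size < sum(tested)) {
    stop("family_size must be at least the number of tested proteins")
  }
  threshold <- if (family_size > 0) alpha / family_size else 0
  out <- data.frame(protein = prots, p_value = p, direction = dirn,
                    flag = tested & !is.na(p) & p <= threshold & alpha > 0,
                    tested = tested)
  attr(out, "threshold") <- threshold
  attr(out, "paired") <- paired
  attr(out, "family_size") <- family_size
  out
}

#' Cluster proteomic samples on their NSAF profiles
#'
#' Delegates to [hierarchical_cluster()] on the NSAF columns (correlation
#' distance over proteins, average linkage, bootstrap support over protein
#' rows).
#'
#' @param nsaf_values matrix from [nsaf()].
#' @param n_boot bootstrap replicates (default 10000).
#' @param ... passed to [hierarchical_cluster()].
#' @return A `boot_hclust` object.
#' @export
cluster_samples <- function(nsaf_values, n_boot = 10000L, ...) {
  if (nrow(nsaf_values) < 2L) {
    stop("need at least 2 proteins (features) to cluster samples")
  }
  hierarchical_cluster(nsaf_values, n_boot = n_boot, ...)
}
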