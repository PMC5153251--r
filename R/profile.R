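#' Chromatographic trace of one sample
#'
#' @param rt retention times in minutes, strictly increasing.
#' @param abundance non-negative abundances (area units).
#' @param sample_id sample identifier.
#' @param colony group identifier (e.g. colony "C11".."C15").
#' @param source `"TF"` (trophallactic fluid) or `"body"` (cuticular
#'   extract).
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(rt, abundance, sample_id = NA_character_,
                         colony = NA_character_, source = NA_character_) {
  stopifnot(length(rt) == length(abundance))
  if (is.unsorted(rt, strictly = TRUE)) {
    stop("retention times must be strictly increasing")
  }
  if (any(abundance < 0)) stop("abundances must be non-negative")
  structure(list(rt = as.numeric(rt), abundance = as.numeric(abundance),
                 sample_id = sample_id, colony = colony, source = source,
                 normalized = FALSE),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s (%s, %s): %d points, Rt %.2f..%.2f min%s\n",
              x$sample_id, x$colony, x$source, length(x$rt), min(x$rt),
              max(x$rt), if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
plot.chromatogram <- function(x, ...) {
  graphics::plot(x$rt, x$abundance, type = "l", xlab = "Rt (min)",
                 ylab = if (x$normalized) "normalized abundance"
                        else "abundance", ...)
  invisible(x)
}

#' Min-max normalization within the analysis window
#'
#' Restricts the trace to the hydrocarbon retention-time window and maps
#' abundance to `(x - min) / (max - min)`, so the normalized trace spans
#' exactly [0, 1]. The default window (36--51 min) covers the C28--C37
#' long-chain hydrocarbons under the GC program this package models.
#'
#' @param chrom a [chromatogram()].
#' @param window numeric length-2, retention-time window in minutes.
#' @return A normalized [chromatogram()] restricted to the window.
#' @export
normalize_profile <- function(chrom, window = c(36, 51)) {
  stopifnot(inherits(chrom, "chromatogram"), length(window) == 2L)
  keep <- chrom$rt >= window[1] & chrom$rt <= window[2]
  if (!any(keep)) stop("window does not overlap the trace")
  x <- chrom$abundance[keep]
  rng <- range(x)
  if (rng[2] <= rng[1]) stop("flat trace in window: cannot normalize")
  out <- chrom
  out$rt <- chrom$rt[keep]
  out$abundance <- (x - rng[1]) / (rng[2] - rng[1])
  out$normalized <- TRUE
  out
}

#' Detect peaks in a normalized chromatogram
#'
#' A peak is a local maximum (strictly greater than both neighbours; on a
#' plateau, its leftmost point) whose normalized abundance reaches the
#' relative threshold. The default threshold of 0.07 retains peaks above 7%
#' of the sample's normalized abundance range.
#'
#' @param chrom a normalized [chromatogram()].
#' @param rel_threshold minimum normalized abundance (default 0.07).
#' @return An object of class `peak_table`: data frame with columns `rt`,
#'   `abundance`.
#' @export
find_peaks <- function(chrom, rel_threshold = 0.07) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (!isTRUE(chrom$normalized)) {
    stop("find_peaks() expects a normalized chromatogram; ",
         "call normalize_profile() first")
  }
  y <- chrom$abundance
  n <- length(y)
  idx <- integer(0)
  if (n >= 3L) {
    d <- diff(y)
    # sign of slope, carrying the last nonzero sign across plateaus
    s <- sign(d)
    for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
    rising_to_falling <- which(s[-1] == -1 & s[-length(s)] == 1) + 1L
    # plateau apexes report their leftmost point
    idx <- vapply(rising_to_falling, function(i) {
      while (i > 1L && d[i - 1L] == 0) i <- i - 1L
      i
    }, integer(1))
    idx <- unique(idx)
  }
  idx <- idx[y[idx] >= rel_threshold]
  structure(data.frame(rt = chrom$rt[idx], abundance = y[idx]),
            class = c("peak_table", "data.frame"))
}

#' Bin peaks by retention time
#'
#' Assigns each peak to `floor((rt - origin) / bin_width)`; peaks sharing a
#' bin are summed. The origin is fixed globally (default 0.0 min) so all
#' samples of a cohort share bin edges; the bin range is taken from
#' `window` so every sample yields a vector of identical length.
#'
#' @param peaks a [find_peaks()] result.
#' @param bin_width bin width in minutes (default 0.03).
#' @param window retention-time window covered by the bins.
#' @param origin global origin for bin edges (default 0).
#' @return An object of class `binned_profile`: numeric vector of per-bin
#'   abundance with attributes `bin_width`, `origin`, `first_bin`.
#' @export
bin_peaks <- function(peaks, bin_width = 0.03, window = c(36, 51),
                      origin = 0) {
  stopifnot(bin_width > 0)
  first_bin <- floor((window[1] - origin) / bin_width)
  last_bin <- floor((window[2] - origin) / bin_width)
  v <- numeric(last_bin - first_bin + 1L)
  if (nrow(peaks)) {
    bins <- floor((peaks$rt - origin) / bin_width)
    keep <- bins >= first_bin & bins <= last_bin
    tab <- tapply(peaks$abundance[keep],
                  factor(bins[keep] - first_bin + 1L,
                         levels = seq_along(v)), sum)
    v[!is.na(tab)] <- tab[!is.na(tab)]
  }
  structure(v, bin_width = bin_width, origin = origin, first_bin = first_bin,
            class = "binned_profile")
}

#' Normalized cross-correlation similarity between binned profiles
#'
#' The coefficient-normalized cross-correlation
#' `sum(p1[i] p2[i + lag]) / (||p1|| ||p2||)`, maximized over integer lags
#' `|lag| <= max_lag` (default 0: no shift search). Symmetric, bounded by 1
#' and invariant to positive scaling of either profile.
#'
#' @param p1,p2 [bin_peaks()] results on identical binning.
#' @param max_lag maximum lag in bins (default 0).
#' @return Similarity value in [-1, 1].
#' @export
xcorr_similarity <- function(p1, p2, max_lag = 0L) {
  v1 <- as.numeric(p1); v2 <- as.numeric(p2)
  if (length(v1) != length(v2)) stop("profiles must share binning")
  if (inherits(p1, "binned_profile") && inherits(p2, "binned_profile")) {
    if (!isTRUE(all.equal(attr(p1, "bin_width"), attr(p2, "bin_width"))) ||
        attr(p1, "first_bin") != attr(p2, "first_bin")) {
      stop("profiles must share binning (width and origin)")
    }
  }
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("undefined similarity: zero-norm profile")
  n <- length(v1)
  best <- -Inf
  for (lag in (-max_lag):max_lag) {
    if (lag >= 0) {
      i1 <- seq_len(n - lag); i2 <- i1 + lag
    } else {
      i2 <- seq_len(n + lag); i1 <- i2 - lag
    }
    best <- max(best, sum(v1[i1] * v2[i2]) / (n1 * n2))
  }
  best
}

#' Pairwise similarity matrix for a cohort of profiles
#'
#' @param profiles named list of [bin_peaks()] results.
#' @param meta data frame with columns `sample_id`, `colony`, `source`
#'   (rows matching `names(profiles)`).
#' @param max_lag passed to [xcorr_similarity()].
#' @return An object of class `similarity_matrix`: the symmetric matrix with
#'   unit diagonal, with the metadata attached.
#' @export
similarity_matrix <- function(profiles, meta, max_lag = 0L) {
  ids <- names(profiles)
  stopifnot(!is.null(ids), all(ids %in% meta$sample_id))
  meta <- meta[match(ids, meta$sample_id), ]
  n <- length(profiles)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- xcorr_similarity(profiles[[i]], profiles[[j]],
                                             max_lag = max_lag)
    }
  }
  structure(m, meta = meta, class = c("similarity_matrix", "matrix"))
}

#' Pairwise similarity partitions (within-TF, within-body, cross)
#'
#' Extracts the upper-triangle similarity values, labelling each pair by
#' partition. Within-source partitions keep only cross-colony pairs, the
#' comparison of interest when asking whether trophallactic-fluid profiles
#' are more uniform across colonies than cuticular ones.
#'
#' @param sim a [similarity_matrix()].
#' @return A data frame with columns `id1`, `id2`, `similarity`, `partition`.
#' @export
similarity_pairs <- function(sim) {
  meta <- attr(sim, "meta")
  ids <- rownames(sim)
  out <- NULL
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      src_i <- meta$source[i]; src_j <- meta$source[j]
      cross_colony <- meta$colony[i] != meta$colony[j]
      part <- if (src_i == src_j && cross_colony) paste0("within-", src_i)
              else if (src_i == src_j) paste0("within-colony-", src_i)
              else "cross"
      out <- rbind(out, data.frame(id1 = ids[i], id2 = ids[j],
                                   similarity = sim[i, j], partition = part))
    }
  }
  out
}

#' Compare within-group similarities between trophallactic fluid and body
#'
#' Two-sample test on the cross-colony pairwise similarities of the two
#' sources. Welch's t-test is the default; a pooled-variance t and a
#' permutation test (exact when feasible, Monte Carlo otherwise) are
#' available -- the permutation route also covers degenerate-variance cases
#' where the t-test is undefined.
#'
#' @param sim a [similarity_matrix()], or a data frame from
#'   [similarity_pairs()].
#' @param sources the two within-source partitions compared (default TF and
#'   body).
#' @param method `"welch"`, `"pooled"` or `"permutation"`.
#' @param n_perm Monte Carlo permutations when exhaustive enumeration
#'   exceeds this count (default 10000).
#' @return A list with group summaries (mean, median, IQR, n), `statistic`,
#'   `p_value`, `method`.
#' @export
compare_groups <- function(sim, sources = c("TF", "body"),
                           method = c("welch", "pooled", "permutation"),
                           n_perm = 10000L) {
  method <- match.arg(method)
  pairs <- if (is.data.frame(sim)) sim else similarity_pairs(sim)
  g1 <- pairs$similarity[pairs$partition == paste0("within-", sources[1])]
  g2 <- pairs$similarity[pairs$partition == paste0("within-", sources[2])]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("need at least 2 cross-colony pairs per partition")
  }
  summarize <- function(x) {
    list(mean = mean(x), median = stats::median(x),
         iqr = stats::quantile(x, c(0.25, 0.75), names = FALSE), n = length(x))
  }
  res <- list(groups = stats::setNames(list(summarize(g1), summarize(g2)),
                                       sources),
              method = method)
  if (method %in% c("welch", "pooled")) {
    if (stats::var(g1) == 0 && stats::var(g2) == 0) {
      stop("degenerate variance in both groups; ",
           "use method = \"permutation\"")
    }
    tt <- stats::t.test(g1, g2, var.equal = (method == "pooled"))
    res$statistic <- unname(tt$statistic)
    res$p_value <- tt$p.value
    res$df <- unname(tt$parameter)
  } else {
    obs <- mean(g1) - mean(g2)
    pooled <- c(g1, g2)
    n1 <- length(g1)
    n_comb <- choose(length(pooled), n1)
    if (n_comb <= n_perm) {
      combs <- utils::combn(length(pooled), n1)
      stat <- apply(combs, 2, function(ix) {
        mean(pooled[ix]) - mean(pooled[-ix])
      })
      res$p_value <- mean(abs(stat) >= abs(obs) - 1e-12)
      res$exact <- TRUE
    } else {
      stat <- replicate(n_perm, {
        ix <- sample.int(length(pooled), n1)
        mean(pooled[ix]) - mean(pooled[-ix])
      })
      res$p_value <- (1 + sum(abs(stat) >= abs(obs) - 1e-12)) / (1 + n_perm)
      res$exact <- FALSE
    }
    res$statistic <- obs
  }
  res
}
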