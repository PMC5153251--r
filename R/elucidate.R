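#' Pair enhanced ions and estimate the methyl-branch count
#'
#' The two diagnostic ions of one methyl branch of a monomethyl alkane of
#' parent mass M are complementary: their m/z values sum to `M + 28`.
#' Enhanced ions are therefore paired greedily (smallest with the matching
#' largest) under that sum constraint, within `pair_tol` Da; a single ion may
#' self-pair when the branch sits at the chain midpoint. The branch-count
#' estimate is the number of pairs.
#'
#' @param enhanced numeric vector of enhanced-ion m/z values (or the data
#'   frame returned by [enhanced_ions()]).
#' @param parent_mass nominal parent mass in Da.
#' @param pair_tol pairing tolerance in Da (default 1).
#' @param target_sum the required pair sum; defaults to `parent_mass + 28`,
#'   exact for monomethyl alkanes.
#' @param observable_min lowest observable series m/z. An unpaired enhanced
#'   ion whose complement falls below this value is paired with that
#'   (unobservable) complement: the low diagnostic ion of a 2- or 3-methyl
#'   branch lies at m/z 43 or 57, inside the low-mass region dominated by
#'   non-specific fragmentation, so only its high-mass partner is visible.
#'   Default `-Inf` disables the rule.
#' @return A list with `k` (number of pairs), `pairs` (two-column matrix,
#'   low/high m/z), and `unpaired` (enhanced ions that could not be paired).
#' @examples
#' estimate_branch_count(c(141, 309), parent_mass = 422)$k # 1
#' @export
estimate_branch_count <- function(enhanced, parent_mass, pair_tol = 1,
                                  target_sum = parent_mass + 28,
                                  observable_min = -Inf) {
  if (is.data.frame(enhanced)) enhanced <- enhanced$mz
  mz <- sort(as.numeric(enhanced))
  pairs <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("low", "high")))
  used <- rep(FALSE, length(mz))
  for (i in seq_along(mz)) {
    if (used[i]) next
    # candidate partners: unused ions (including i itself, the midpoint case)
    j_cand <- which(!used & seq_along(mz) >= i &
                      abs(mz + mz[i] - target_sum) <= pair_tol)
    if (!length(j_cand)) next
    j <- j_cand[which.min(abs(mz[j_cand] + mz[i] - target_sum))]
    pairs <- rbind(pairs, c(mz[i], mz[j]))
    used[i] <- TRUE; used[j] <- TRUE
  }
  if (is.finite(observable_min)) {
    for (i in which(!used)) {
      comp <- target_sum - mz[i]
      if (comp < observable_min && comp >= 43 - pair_tol) {
        pairs <- rbind(pairs, c(comp, mz[i]))
        used[i] <- TRUE
      }
    }
  }
  unpaired <- mz[!used]
  if (length(mz) && nrow(pairs) == 0L) {
    warning("enhanced ions present but none pairable at sum ", target_sum)
  }
  list(k = nrow(pairs), pairs = pairs, unpaired = unpaired)
}

#' Invert diagnostic-ion pairs to branch positions
#'
#' For a pair whose low-mass ion is `m_low`, the branch locant is
#' `b = (m_low - 15) / 14`; non-integer solutions reject the pair. The
#' backbone length follows from the parent mass and the number of branches
#' (`L = (M - 2)/14 - k`, i.e. `(M - 16)/14` for monomethyl). When several
#' branches are present, each pair constrains its locant only up to the
#' choice of chain end, so all end-assignments are enumerated, canonicalized
#' and deduplicated; more than one surviving structure is flagged ambiguous.
#'
#' @param pairs two-column matrix from [estimate_branch_count()] (columns
#'   low/high m/z).
#' @param parent_mass nominal parent mass in Da; must be that of a CnH2n+2
#'   alkane (`M = 14 n + 2`).
#' @return A list of candidate [hydrocarbon()] structures (possibly empty).
#' @examples
#' bp <- estimate_branch_count(c(141, 309), 422)
#' infer_branch_positions(bp$pairs, 422) # 9-methylnonacosane
#' @export
infer_branch_positions <- function(pairs, parent_mass) {
  if ((parent_mass - 2) %% 14 != 0) {
    stop("parent mass ", parent_mass, " is not a CnH2n+2 alkane mass")
  }
  n_total <- (parent_mass - 2) %/% 14
  k <- nrow(pairs)
  if (k == 0L) {
    return(list(hydrocarbon(n_total)))
  }
  L <- n_total - k
  b_low <- (pairs[, "low"] - 15) / 14
  ok <- b_low == round(b_low) & b_low > 1 & b_low < L
  if (!all(ok)) return(list())
  b_low <- as.integer(round(b_low))
  # each branch can be numbered from either end; enumerate assignments
  choices <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  cands <- lapply(seq_len(nrow(choices)), function(i) {
    flip <- unlist(choices[i, ])
    b <- ifelse(flip, L + 1L - b_low, b_low)
    if (anyDuplicated(b)) return(NULL)
    hydrocarbon(L, b)
  })
  cands <- Filter(Negate(is.null), cands)
  keys <- vapply(cands, function(s) paste(s$branch_positions, collapse = ","),
                 character(1))
  cands <- cands[!duplicated(keys)]
  if (length(cands) > 1L) {
    cands <- lapply(cands, function(s) { s$ambiguous <- TRUE; s })
  }
  cands
}

#' Full structure elucidation of one chromatographic peak
#'
#' Chains the elucidation workflow for saturated hydrocarbons: extract the
#' alkyl fragment series, fit the exponential decay envelope, collect
#' enhanced ions, pair them to estimate the number of methyl branches,
#' invert the pairs to branch locants, and check the resulting hypothesis
#' against the retention-index reference curves. When the monomethyl pair
#' sum yields no consistent pairing, pair sums for higher branch counts
#' (`M + 42 - 14 k`, the complement sum implied by the diagnostic-ion model
#' for k branches) are tried and the self-consistent k (pair count equal to
#' k) is kept.
#'
#' @param spectrum an [ei_spectrum()]; `parent_mass` must be set (directly
#'   or via the `parent_mass` argument).
#' @param rt retention time in minutes (defaults to `spectrum$rt`).
#' @param ladder an [alkane_ladder()] for the retention index.
#' @param curves an optional [build_ri_curves()] result for the consistency
#'   check.
#' @param parent_mass optional override of the spectrum's parent mass.
#' @param tau enhancement threshold (default 3).
#' @param pair_tol pairing tolerance in Da (default 1).
#' @param ri_tol retention-index consistency tolerance (default 15).
#' @param max_fit_iterations outlier-aware refit rounds (default 5).
#' @return An object of class `elucidation`: `branch_count`, `candidates`
#'   (list of [hydrocarbon()]), `enhanced` (data frame), `fit`
#'   ([fit_decay()] result), `ri` (observed retention index or NA),
#'   `ri_check` (per-candidate verdicts), `inconclusive` plus `reason`.
#' @export
identify_compound <- function(spectrum, rt = spectrum$rt, ladder = NULL,
                              curves = NULL, parent_mass = NULL,
                              tau = 3, pair_tol = 1, ri_tol = 15,
                              max_fit_iterations = 5L) {
  stopifnot(inherits(spectrum, "ei_spectrum"))
  M <- if (!is.null(parent_mass)) parent_mass else spectrum$parent_mass
  if (is.null(M)) stop("parent mass is required for elucidation")
  if (is.null(spectrum$parent_mass)) spectrum$parent_mass <- M

  res <- list(branch_count = NA_integer_, candidates = list(),
              enhanced = NULL, fit = NULL, ri = NA_real_, ri_check = NULL,
              inconclusive = FALSE, reason = NULL)
  class(res) <- "elucidation"

  series <- tryCatch(alkyl_series(spectrum), error = function(e) e)
  if (inherits(series, "error")) {
    res$inconclusive <- TRUE
    res$reason <- paste("alkyl_series:", conditionMessage(series))
    return(res)
  }
  fit <- tryCatch(
    withCallingHandlers(
      fit_decay(series, tau = tau, max_iter = max_fit_iterations),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) e)
  if (inherits(fit, "error")) {
    res$inconclusive <- TRUE
    res$reason <- paste("fit_decay:", conditionMessage(fit))
    return(res)
  }
  res$fit <- fit
  if (fit$flat) {
    res$inconclusive <- TRUE
    res$reason <- "flat spectrum: no decaying envelope"
    return(res)
  }
  enh <- enhanced_ions(fit, tau = tau)
  res$enhanced <- enh

  if (nrow(enh) == 0L) {
    pairing <- list(k = 0L, pairs = matrix(numeric(0), ncol = 2,
                                           dimnames = list(NULL,
                                                           c("low", "high"))),
                    unpaired = numeric(0))
  } else {
    obs_min <- fit$domain[1]
    pairing <- suppressWarnings(
      estimate_branch_count(enh, M, pair_tol = pair_tol,
                            observable_min = obs_min))
    if (pairing$k == 0L || length(pairing$unpaired)) {
      # monomethyl sum did not account for everything: try k-specific sums
      for (k_try in 2:5) {
        alt <- suppressWarnings(
          estimate_branch_count(enh, M, pair_tol = pair_tol,
                                target_sum = M + 42 - 14 * k_try,
                                observable_min = obs_min))
        if (alt$k == k_try && length(alt$unpaired) == 0L) {
          pairing <- alt
          break
        }
      }
    }
  }
  res$branch_count <- pairing$k
  res$unpaired <- pairing$unpaired
  cands <- infer_branch_positions(pairing$pairs, M)
  res$candidates <- cands

  if (!is.null(ladder) && !is.null(rt)) {
    ri <- tryCatch(retention_index(rt, ladder), error = function(e) NA_real_)
    res$ri <- ri
    if (!is.null(curves) && !is.na(ri) && length(cands)) {
      res$ri_check <- lapply(cands, check_consistency,
                             observed_ri = ri, curves = curves, tol = ri_tol)
    }
  }
  res
}

#' @export
print.elucidation <- function(x, ...) {
  cat("<elucidation>\n")
  if (x$inconclusive) {
    cat("  inconclusive:", x$reason, "\n")
    return(invisible(x))
  }
  cat("  branch count:", x$branch_count, "\n")
  if (!is.null(x$enhanced) && nrow(x$enhanced)) {
    cat("  enhanced ions:",
        paste(sprintf("%g (x%.1f)", x$enhanced$mz, x$enhanced$ratio),
              collapse = ", "), "\n")
  }
  for (i in seq_along(x$candidates)) {
    cat("  candidate:", format(x$candidates[[i]]))
    if (!is.null(x$ri_check)) {
      chk <- x$ri_check[[i]]
      cat(sprintf("  [RI %s, deviation %.1f]", chk$verdict,
                  if (is.na(chk$deviation)) NA else chk$deviation))
    }
    cat("\n")
  }
  if (!is.na(x$ri)) cat(sprintf("  observed RI: %.1f\n", x$ri))
  invisible(x)
}
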