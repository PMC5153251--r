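#' n-Alkane calibration ladder
#'
#' Retention times of a linear-alkane standard mixture (e.g. C8--C40), used to
#' convert retention times into Kovats retention indices.
#'
#' @param carbon_number integer vector, strictly increasing.
#' @param rt_min retention times in minutes, strictly increasing.
#' @return An object of class `alkane_ladder` (a data frame).
#' @export
alkane_ladder <- function(carbon_number, rt_min) {
  n <- as.integer(carbon_number)
  rt <- as.numeric(rt_min)
  if (length(n) < 2L) stop("ladder needs at least 2 entries")
  if (length(n) != length(rt)) stop("carbon_number and rt_min lengths differ")
  if (any(diff(n) <= 0L)) stop("carbon numbers must be strictly increasing")
  if (any(diff(rt) <= 0)) stop("retention times must be strictly increasing")
  structure(data.frame(carbon_number = n, rt_min = rt),
            class = c("alkane_ladder", "data.frame"))
}

#' Kovats retention index by linear interpolation
#'
#' Uses the van den Dool--Kratz (linear) formula appropriate for
#' temperature-programmed GC: with bracketing alkanes `(n1, rt1)` and
#' `(n2, rt2)`, `RI = 100 n1 + 100 (n2 - n1) (rt - rt1) / (rt2 - rt1)`.
#' When the bracketing carbon numbers are not consecutive the interpolation
#' spans the gap and a warning is emitted. The n-alkane with n carbons maps
#' exactly to `100 n`, and the index is invariant to a common shift of all
#' retention times.
#'
#' @param rt retention time(s) in minutes; must lie within the ladder span.
#' @param ladder an [alkane_ladder()].
#' @return Numeric RI value(s). Use [ri_round()] for the integer convention.
#' @examples
#' lad <- alkane_ladder(c(15, 16), c(13.35, 15.05))
#' ri_round(retention_index(14.05, lad)) # 1541
#' @export
retention_index <- function(rt, ladder) {
  stopifnot(inherits(ladder, "alkane_ladder"))
  rt <- as.numeric(rt)
  lo <- ladder$rt_min[1L]; hi <- ladder$rt_min[nrow(ladder)]
  if (any(rt < lo | rt > hi)) {
    stop(sprintf("retention time outside ladder span [%.3f, %.3f] min", lo, hi))
  }
  i <- findInterval(rt, ladder$rt_min, rightmost.closed = TRUE)
  n1 <- ladder$carbon_number[i]; n2 <- ladder$carbon_number[i + 1L]
  rt1 <- ladder$rt_min[i]; rt2 <- ladder$rt_min[i + 1L]
  gap <- n2 - n1
  if (any(gap > 1L, na.rm = TRUE)) {
    warning("ladder has gaps in carbon number; interpolating across them")
  }
  at_node <- rt == rt1
  ri <- ifelse(at_node, 100 * n1,
               100 * n1 + 100 * gap * (rt - rt1) / (rt2 - rt1))
  as.numeric(ri)
}

#' Round a retention index to the integer convention (half-up)
#' @param ri numeric RI value(s).
#' @return Integer RI.
#' @export
ri_round <- function(ri) as.integer(floor(ri + 0.5))

#' Reference RI curves per methyl-branching class
#'
#' Builds, for each branch count k = 0 (linear) up to 5 (pentamethylated),
#' a piecewise-linear curve of mean reference RI against total carbon number,
#' from a table of literature RI values.
#'
#' @param reference a data frame with columns `carbons`, `branches`, `ri`
#'   (one row per literature value; several rows per (carbons, branches) are
#'   averaged).
#' @return An object of class `ri_curve_set`.
#' @examples
#' ref <- data.frame(carbons = c(25, 25, 25), branches = 2,
#'                   ri = c(2405, 2409, 2413))
#' curves <- build_ri_curves(ref)
#' predict(curves, carbons = 25, branches = 2) # 2409
#' @export
build_ri_curves <- function(reference) {
  need <- c("carbons", "branches", "ri")
  if (!all(need %in% names(reference))) {
    stop("reference table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(reference$branches < 0 | reference$branches > 5)) {
    stop("branch counts must lie in 0..5")
  }
  agg <- stats::aggregate(ri ~ carbons + branches, data = reference, FUN = mean)
  curves <- lapply(sort(unique(agg$branches)), function(k) {
    sub <- agg[agg$branches == k, ]
    sub <- sub[order(sub$carbons), ]
    if (any(diff(sub$ri) <= 0)) {
      bad <- sub$carbons[c(FALSE, diff(sub$ri) <= 0)]
      stop("mean RI not strictly increasing for branch count ", k,
           " at carbon number(s): ", paste(bad, collapse = ", "))
    }
    sub
  })
  names(curves) <- sort(unique(agg$branches))
  structure(list(curves = curves), class = "ri_curve_set")
}

#' @export
print.ri_curve_set <- function(x, ...) {
  cat("<RI curve set> branch classes:",
      paste(names(x$curves), collapse = ", "), "\n")
  for (k in names(x$curves)) {
    sub <- x$curves[[k]]
    cat(sprintf("  k=%s: C%d..C%d (%d points)\n", k, min(sub$carbons),
                max(sub$carbons), nrow(sub)))
  }
  invisible(x)
}

#' Evaluate a reference RI curve
#'
#' @param object an [build_ri_curves()] result.
#' @param carbons total carbon number(s) at which to evaluate.
#' @param branches branch count (single value, 0..5).
#' @param ... unused.
#' @return Numeric RI value(s); `NA` outside the curve's carbon span.
#' @export
predict.ri_curve_set <- function(object, carbons, branches, ...) {
  sub <- object$curves[[as.character(branches)]]
  if (is.null(sub)) {
    stop("no reference curve for branch count ", branches)
  }
  if (nrow(sub) == 1L) {
    return(ifelse(carbons == sub$carbons, sub$ri, NA_real_))
  }
  stats::approx(sub$carbons, sub$ri, xout = carbons, rule = 1)$y
}

#' Check a structural hypothesis against the RI curves
#'
#' Compares an observed retention index with the reference curve for the
#' hypothesis's branching class at its total carbon number. Carbon counts
#' outside the curve span give an `"inconclusive"` verdict, distinct from
#' `"fail"`.
#'
#' @param hypothesis a saturated [hydrocarbon()] (or a list with elements
#'   `carbons` and `branches`).
#' @param observed_ri observed retention index.
#' @param curves an [build_ri_curves()] result.
#' @param tol tolerance in RI units (default 15).
#' @return A list with `verdict` ("pass"/"fail"/"inconclusive"),
#'   `deviation`, `expected`, `tol`.
#' @export
check_consistency <- function(hypothesis, observed_ri, curves, tol = 15) {
  if (inherits(hypothesis, "hydrocarbon")) {
    carbons <- hypothesis$backbone_length + length(hypothesis$branch_positions)
    branches <- length(hypothesis$branch_positions)
  } else {
    carbons <- hypothesis$carbons; branches <- hypothesis$branches
  }
  expected <- predict(curves, carbons = carbons, branches = branches)
  if (is.na(expected)) {
    return(list(verdict = "inconclusive", deviation = NA_real_,
                expected = NA_real_, tol = tol))
  }
  dev <- observed_ri - expected
  list(verdict = if (abs(dev) <= tol) "pass" else "fail",
       deviation = dev, expected = expected, tol = tol)
}
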