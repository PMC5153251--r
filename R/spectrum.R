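#' Electron-impact mass spectrum of one chromatographic peak
#'
#' @param mz m/z values (canonicalized to strictly increasing order;
#'   duplicate m/z intensities are summed).
#' @param intensity non-negative intensities (arbitrary units).
#' @param parent_mass optional nominal parent mass in Da.
#' @param rt optional retention time in minutes.
#' @return An object of class `ei_spectrum`.
#' @export
ei_spectrum <- function(mz, intensity, parent_mass = NULL, rt = NULL) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be non-negative")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)),
                                   sum))
    mz <- unique(mz)
  }
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 parent_mass = parent_mass, rt = rt),
            class = "ei_spectrum")
}

#' @export
print.ei_spectrum <- function(x, ...) {
  cat("<EI spectrum> ", length(x$mz), " peaks, m/z ",
      min(x$mz), "..", max(x$mz), sep = "")
  if (!is.null(x$parent_mass)) cat(", parent", x$parent_mass, "Da")
  if (!is.null(x$rt)) cat(", Rt", x$rt, "min")
  cat("\n")
  invisible(x)
}

#' Extract the alkyl fragment series from an EI spectrum
#'
#' Saturated-alkane EI spectra are dominated by the CnH2n+1 ladder at
#' m/z 43, 57, 71, ... = 14 n + 1 (n >= 3). Spectrum peaks are matched to
#' series positions within +/- 0.5 m/z; series members with no matching peak
#' are recorded as absent (`present = FALSE`), not as zero intensity. The
#' series runs up to `parent_mass - 15` when the parent is known, otherwise
#' up to the largest observed m/z.
#'
#' @param spectrum an [ei_spectrum()].
#' @param min_members minimum number of present members required (default 4).
#' @return A data frame with columns `n`, `mz` (nominal series m/z),
#'   `intensity`, `present`.
#' @export
alkyl_series <- function(spectrum, min_members = 4L) {
  stopifnot(inherits(spectrum, "ei_spectrum"))
  top <- if (!is.null(spectrum$parent_mass)) spectrum$parent_mass - 15
         else max(spectrum$mz)
  n_max <- floor((top - 1) / 14)
  if (n_max < 3L) stop("insufficient alkyl series: spectrum span too small")
  n <- 3:n_max
  target <- 14 * n + 1
  idx <- vapply(target, function(m) {
    d <- abs(spectrum$mz - m)
    j <- which.min(d)
    if (d[j] <= 0.5) j else NA_integer_
  }, integer(1))
  out <- data.frame(n = n, mz = target,
                    intensity = ifelse(is.na(idx), NA_real_,
                                       spectrum$intensity[idx]),
                    present = !is.na(idx))
  if (sum(out$present) < min_members) {
    stop("insufficient alkyl series: only ", sum(out$present),
         " members found (need ", min_members, ")")
  }
  out
}
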