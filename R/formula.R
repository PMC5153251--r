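#' Molecular formulas and nominal mass arithmetic
#'
#' A `molecular_formula` is a named integer vector of element counts
#' (e.g. `c(C = 30, H = 62)`). Only nominal (integer) masses are used
#' throughout the package; this matches the unit-resolution EI spectra the
#' elucidation workflow consumes.
#'
#' @param ... element counts given as named arguments, e.g.
#'   `molecular_formula(C = 30, H = 62)`, or a single named numeric vector.
#' @return An object of class `molecular_formula`.
#' @examples
#' molecular_formula(C = 23, H = 48)
#' nominal_mass(molecular_formula(C = 23, H = 48)) # 324
#' @export
molecular_formula <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    counts <- args[[1]]
  } else {
    counts <- unlist(args)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("element counts must be named (e.g. C = 30, H = 62)")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers")
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("formula must contain at least one atom")
  structure(as.integer(counts), names = names(counts),
            class = "molecular_formula")
}

# nominal (integer) masses of the elements this package handles
.nominal_masses <- c(C = 12L, H = 1L, O = 16L, N = 14L, S = 32L)

#' Nominal mass of a molecular formula
#'
#' @param formula a [molecular_formula()] or a formula string such as
#'   `"C30H62"`.
#' @return Integer mass in Da (C = 12, H = 1, O = 16).
#' @examples
#' nominal_mass("C37H76") # 520
#' @export
nominal_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "molecular_formula"))
  unknown <- setdiff(names(formula), names(.nominal_masses))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(.nominal_masses[names(formula)] * as.integer(formula))
}

#' Parse a Hill-style formula string
#'
#' @param x a string such as `"C16H32O2"`.
#' @return A [molecular_formula()].
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tokens <- regmatches(x, gregexpr("[A-Z][a-z]?[0-9]*", x))[[1]]
  if (!length(tokens) || nchar(paste(tokens, collapse = "")) != nchar(x)) {
    stop("cannot parse formula: ", x)
  }
  els <- gsub("[0-9]", "", tokens)
  ns <- suppressWarnings(as.integer(gsub("[^0-9]", "", tokens)))
  ns[is.na(ns)] <- 1L
  counts <- tapply(ns, factor(els, levels = unique(els)), sum)
  molecular_formula(structure(as.integer(counts), names = names(counts)))
}

#' @export
format.molecular_formula <- function(x, ...) {
  # Hill order: C, H, then alphabetical
  els <- names(x)
  ord <- order(match(els, c("C", "H"), nomatch = 3L), els)
  paste0(els[ord], ifelse(x[ord] == 1L, "", x[ord]), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular formula> ", format(x), "  (nominal mass ",
      nominal_mass(x), " Da)\n", sep = "")
  invisible(x)
}

#' @export
as.character.molecular_formula <- function(x, ...) format(x)
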