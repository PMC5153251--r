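#' Hydrocarbon structures
#'
#' A `hydrocarbon` describes a linear or methyl-branched chain: the backbone
#' length `L` (carbons in the main chain), the methyl-branch locants on that
#' backbone, and the number of double bonds. Branch locants are always
#' canonicalized to the lowest-locant numbering of the chain (IUPAC
#' convention), so `hydrocarbon(29, 21)` and `hydrocarbon(29, 9)` are the
#' same molecule, stored with branch position 9. Non-hydrocarbon compounds
#' (fatty acids, esters, an aldehyde, a sterol-like molecule) that co-occur
#' in trophallactic fluid are carried as annotated records via `other_class`;
#' formula arithmetic is not defined for them and fragment prediction refuses
#' them.
#'
#' @param backbone_length integer, carbons in the main chain (`L`).
#' @param branch_positions integer vector of methyl locants, each strictly
#'   between 1 and `backbone_length`; may be empty. `NA` marks a branch whose
#'   position is unresolved (rendered with the `*-` prefix).
#' @param n_double_bonds non-negative integer.
#' @param other_class optional tag for non-hydrocarbons (annotation only).
#' @param ambiguous logical; `TRUE` when branch/double-bond positions are not
#'   fully resolved.
#' @return An object of class `hydrocarbon`.
#' @examples
#' hydrocarbon(29, 9)                       # 9-methylnonacosane
#' formula_of(hydrocarbon(29, 9))           # C30H62
#' diagnostic_ions(hydrocarbon(29, 9))      # 141, 309
#' @export
hydrocarbon <- function(backbone_length, branch_positions = integer(),
                        n_double_bonds = 0L, other_class = NULL,
                        ambiguous = FALSE) {
  L <- as.integer(backbone_length)
  stopifnot(length(L) == 1L, L >= 1L)
  b <- as.integer(branch_positions)
  known <- b[!is.na(b)]
  if (any(known <= 1L) || any(known >= L)) {
    stop("branch positions must satisfy 1 < b < backbone_length")
  }
  if (anyDuplicated(known)) stop("duplicated branch positions")
  # lowest-locant canonicalization: compare the sorted locant vector with the
  # sorted vector obtained by numbering from the other end
  if (length(known) && length(known) == length(b)) {
    fwd <- sort(known)
    rev_ <- sort(L + 1L - known)
    cmp <- fwd - rev_
    first <- which(cmp != 0)[1]
    if (!is.na(first) && cmp[first] > 0) b <- rev_ else b <- fwd
  } else {
    b <- b[order(b, na.last = TRUE)]
  }
  structure(
    list(backbone_length = L,
         branch_positions = b,
         n_double_bonds = as.integer(n_double_bonds),
         other_class = other_class,
         ambiguous = isTRUE(ambiguous) || anyNA(b)),
    class = "hydrocarbon")
}

is_pure_hydrocarbon <- function(x) {
  inherits(x, "hydrocarbon") && is.null(x$other_class)
}

#' Molecular formula of a hydrocarbon structure
#'
#' Total carbons are backbone plus one per methyl branch; hydrogens follow
#' CnH(2n+2) minus two per double bond.
#'
#' @param structure a [hydrocarbon()].
#' @return A [molecular_formula()].
#' @export
formula_of <- function(structure) {
  stopifnot(inherits(structure, "hydrocarbon"))
  if (!is.null(structure$other_class)) {
    stop("formula_of() is only defined for pure hydrocarbons (other_class = ",
         structure$other_class, ")")
  }
  n_c <- structure$backbone_length + length(structure$branch_positions)
  n_h <- 2L * n_c + 2L - 2L * structure$n_double_bonds
  molecular_formula(C = n_c, H = n_h)
}

#' Diagnostic fragment ions of a methyl-branched alkane
#'
#' Cleavage on either side of a branch carbon produces an enhanced pair of
#' even-electron ions. For a branch at locant `b` on a backbone of length `L`
#' the pair is `14 b + 15` and `14 (L - b + 2) + 1`; at the chain midpoint the
#' two coincide. The union over all branches is returned, sorted. An
#' unbranched alkane gives an empty set (not an error); unsaturated
#' structures are refused, since the model is defined for saturated alkanes.
#'
#' @param structure a saturated [hydrocarbon()].
#' @return Sorted integer vector of m/z values.
#' @examples
#' diagnostic_ions(hydrocarbon(29, 9))   # c(141, 309)
#' diagnostic_ions(hydrocarbon(29, 15))  # 225 (midpoint)
#' @export
diagnostic_ions <- function(structure) {
  stopifnot(inherits(structure, "hydrocarbon"))
  if (!is.null(structure$other_class)) {
    stop("diagnostic ions are only defined for alkanes (other_class = ",
         structure$other_class, ")")
  }
  if (structure$n_double_bonds > 0L) {
    stop("diagnostic ions are not defined for unsaturated structures")
  }
  b <- structure$branch_positions
  if (anyNA(b)) stop("branch positions must be resolved to predict ions")
  if (!length(b)) return(integer())
  L <- structure$backbone_length
  sort(unique(c(14L * b + 15L, 14L * (L - b + 2L) + 1L)))
}

#' @export
print.hydrocarbon <- function(x, ...) {
  cat("<hydrocarbon> ", format(x), sep = "")
  if (is_pure_hydrocarbon(x)) {
    f <- formula_of(x)
    cat("  [", format(f), ", ", nominal_mass(f), " Da]", sep = "")
  }
  cat("\n")
  invisible(x)
}

# ---- naming ----------------------------------------------------------------

.alkane_stems <- c(
  "8" = "octa", "9" = "nona", "10" = "deca", "11" = "undeca",
  "12" = "dodeca", "13" = "trideca", "14" = "tetradeca", "15" = "pentadeca",
  "16" = "hexadeca", "17" = "heptadeca", "18" = "octadeca", "19" = "nonadeca",
  "20" = "eicosa", "21" = "heneicosa", "22" = "docosa", "23" = "tricosa",
  "24" = "tetracosa", "25" = "pentacosa", "26" = "hexacosa",
  "27" = "heptacosa", "28" = "octacosa", "29" = "nonacosa",
  "30" = "triaconta", "31" = "hentriaconta", "32" = "dotriaconta",
  "33" = "tritriaconta", "34" = "tetratriaconta", "35" = "pentatriaconta",
  "36" = "hexatriaconta", "37" = "heptatriaconta", "38" = "octatriaconta",
  "39" = "nonatriaconta", "40" = "tetraconta")

.methyl_multipliers <- c("methyl", "dimethyl", "trimethyl", "tetramethyl",
                         "pentamethyl")

#' Format a hydrocarbon as a systematic name
#'
#' Produces names in the style of the compound tables this package reads
#' ("9-methylnonacosane", "5,9-dimethylhentriacontane"); unresolved positions
#' are rendered with a leading asterisk ("*-pentacosene").
#'
#' @param x a [hydrocarbon()].
#' @param ... unused.
#' @return A character string.
#' @export
format.hydrocarbon <- function(x, ...) {
  if (!is.null(x$other_class)) return(x$other_class)
  stem <- .alkane_stems[as.character(x$backbone_length)]
  if (is.na(stem)) stop("no name stem for backbone length ", x$backbone_length)
  # the stem's final 'a' elides before the -ane/-ene vowel suffixes
  base <- sub("a$", "", stem)
  suffix <- if (x$n_double_bonds == 0L) "ane"
            else if (x$n_double_bonds == 1L) "ene"
            else "adiene"
  k <- length(x$branch_positions)
  if (k == 0L) {
    body <- paste0(base, suffix)
    if (x$ambiguous) paste0("*-", body) else
      paste0(toupper(substr(body, 1, 1)), substr(body, 2, nchar(body)))
  } else {
    mult <- .methyl_multipliers[k]
    locants <- if (anyNA(x$branch_positions) || x$ambiguous) "*"
               else paste(x$branch_positions, collapse = ",")
    paste0(locants, "-", mult, base, suffix)
  }
}

#' Parse a systematic hydrocarbon name
#'
#' Understands linear and methyl-branched alkanes/alkenes
#' ("Tricosane", "5-methylpentadecane", "2,10-dimethyloctacosane") and the
#' asterisk convention for unresolved positions ("*-pentacosene",
#' "*-trimethyloctadecane"). Anything else (acids, esters, aldehydes,
#' sterol-like molecules) is returned as an annotated non-hydrocarbon record.
#'
#' @param name a compound name.
#' @return A [hydrocarbon()].
#' @examples
#' parse_hydrocarbon_name("9-methylnonacosane")
#' parse_hydrocarbon_name("*-pentacosene")
#' @export
parse_hydrocarbon_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  x <- trimws(name)
  # strip parenthesized qualifiers ("(likely 4-)", "(possibly ...)")
  core <- trimws(sub("\\s*\\(.*\\)$", "", x))
  stem_rx <- paste(sub("a$", "", .alkane_stems), collapse = "|")
  rx <- paste0("^(\\*|[0-9]+(?:,[0-9]+)*)?-?(",
               paste(.methyl_multipliers, collapse = "|"),
               ")?(", stem_rx, ")(ane|ene|adiene)$")
  m <- regexec(rx, core, ignore.case = TRUE)
  parts <- regmatches(core, m)[[1]]
  if (!length(parts)) {
    return(hydrocarbon(1L, other_class = x))
  }
  locants <- parts[2]; mult <- tolower(parts[3]); stem <- tolower(parts[4])
  suffix <- tolower(parts[5])
  L <- as.integer(names(.alkane_stems)[match(stem,
                                             sub("a$", "", .alkane_stems))])
  ndb <- switch(suffix, ane = 0L, ene = 1L, adiene = 2L)
  k <- if (nzchar(mult)) match(mult, .methyl_multipliers) else 0L
  ambiguous <- identical(locants, "*")
  b <- if (k == 0L) integer()
       else if (ambiguous || !nzchar(locants)) rep(NA_integer_, k)
       else as.integer(strsplit(locants, ",")[[1]])
  if (!ambiguous && length(b) && !anyNA(b) && length(b) != k) {
    stop("locant count does not match multiplier in name: ", name)
  }
  hydrocarbon(L, b, n_double_bonds = ndb,
              ambiguous = ambiguous || (ndb > 0L && ambiguous))
}
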