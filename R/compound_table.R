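#' Compounds identified by GC-MS in Camponotus trophallactic fluid
#'
#' Returns the packaged table of the 61 compounds identified in trophallactic
#' fluid: retention time, printed molecular weight, proposed molecular
#' formula, proposed structure (asterisks marking unresolved branch or
#' double-bond positions), retention index, chromatogram peak letter and a
#' flag for the three compounds found only in trophallactic fluid and not on
#' the cuticle. Two derived columns are computed on load: `mw_computed`, the
#' nominal mass from the proposed formula, and `mw_discrepant`, flagging the
#' single row whose printed molecular weight disagrees with its printed
#' formula (C21H44, printed 295 vs computed 296); both values are retained
#' rather than silently correcting either.
#'
#' @param path optional path to a compound table CSV with the same columns;
#'   defaults to the packaged table.
#' @return A data frame with columns `rt_min`, `mw_printed`, `formula`,
#'   `structure`, `ri`, `peak_id`, `tf_only`, `mw_computed`, `mw_discrepant`.
#' @examples
#' tab <- tf_compound_table()
#' nrow(tab)            # 61
#' sum(tab$tf_only)     # 3
#' @export
tf_compound_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tf_compound_table.csv",
                        package = "trophochem", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$tf_only <- as.logical(tab$tf_only)
  tab$mw_computed <- vapply(tab$formula,
                            function(f) nominal_mass(parse_formula(f)),
                            integer(1), USE.NAMES = FALSE)
  tab$mw_discrepant <- tab$mw_computed != tab$mw_printed
  tab
}

#' n-Alkane ladder embedded in a compound table
#'
#' Extracts the linear-alkane rows (RI a multiple of 100, saturated,
#' unbranched) of a compound table and assembles them into an
#' [alkane_ladder()]. This reconstructs the calibration that places every
#' other compound on the retention-index scale.
#'
#' @param tab a data frame as returned by [tf_compound_table()].
#' @return An [alkane_ladder()].
#' @export
ladder_from_table <- function(tab) {
  keep <- vapply(seq_len(nrow(tab)), function(i) {
    s <- parse_hydrocarbon_name(tab$structure[i])
    is_pure_hydrocarbon(s) && length(s$branch_positions) == 0L &&
      s$n_double_bonds == 0L && !s$ambiguous &&
      tab$ri[i] == 100L * s$backbone_length
  }, logical(1))
  sub <- tab[keep, ]
  alkane_ladder(sub$ri / 100L, sub$rt_min)
}
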