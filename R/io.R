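#' Read an n-alkane ladder CSV
#'
#' Expected columns: `carbon_number`, `rt_min` (headered, UTF-8, dot
#' decimal).
#'
#' @param path CSV path.
#' @return An [alkane_ladder()].
#' @export
read_ladder_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("carbon_number", "rt_min")
  if (!all(need %in% names(d))) {
    stop("ladder CSV ", path, " needs columns: ", paste(need, collapse = ", "))
  }
  alkane_ladder(d$carbon_number, d$rt_min)
}

#' Write an n-alkane ladder CSV
#' @param ladder an [alkane_ladder()].
#' @param path output path.
#' @export
write_ladder_csv <- function(ladder, path) {
  utils::write.csv(as.data.frame(ladder), path, row.names = FALSE)
}

#' Read a reference RI table CSV
#'
#' Expected columns: `carbons`, `branches`, `ri`.
#'
#' @param path CSV path.
#' @return A data frame suitable for [build_ri_curves()].
#' @export
read_ri_reference_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("carbons", "branches", "ri")
  if (!all(need %in% names(d))) {
    stop("reference RI CSV ", path, " needs columns: ",
         paste(need, collapse = ", "))
  }
  d
}

#' Read EI spectra from CSV
#'
#' Either one file per peak with columns `mz`, `intensity`, or a long-format
#' file with an additional `peak_id` column.
#'
#' @param path CSV path.
#' @param parent_mass optional parent mass (single value, or named by
#'   peak id for long format).
#' @return An [ei_spectrum()], or a named list of them for long format.
#' @export
read_spectrum_csv <- function(path, parent_mass = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("mz", "intensity") %in% names(d))) {
    stop("spectrum CSV ", path, " needs columns mz, intensity")
  }
  if ("peak_id" %in% names(d)) {
    ids <- unique(d$peak_id)
    out <- lapply(ids, function(id) {
      sub <- d[d$peak_id == id, ]
      pm <- if ("parent_mass" %in% names(sub)) sub$parent_mass[1]
            else if (!is.null(parent_mass)) parent_mass[[as.character(id)]]
            else NULL
      rt <- if ("rt_min" %in% names(sub)) sub$rt_min[1] else NULL
      ei_spectrum(sub$mz, sub$intensity, parent_mass = pm, rt = rt)
    })
    names(out) <- ids
    out
  } else {
    pm <- if ("parent_mass" %in% names(d)) d$parent_mass[1] else parent_mass
    rt <- if ("rt_min" %in% names(d)) d$rt_min[1] else NULL
    ei_spectrum(d$mz, d$intensity, parent_mass = pm, rt = rt)
  }
}

#' Write an EI spectrum to CSV
#' @param spectrum an [ei_spectrum()].
#' @param path output path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  d <- data.frame(mz = spectrum$mz, intensity = spectrum$intensity)
  if (!is.null(spectrum$parent_mass)) d$parent_mass <- spectrum$parent_mass
  if (!is.null(spectrum$rt)) d$rt_min <- spectrum$rt
  utils::write.csv(d, path, row.names = FALSE)
}

#' Read a chromatogram sample CSV
#'
#' Expected columns: `rt_min`, `abundance`.
#'
#' @param path CSV path.
#' @param sample_id,colony,source metadata attached to the trace.
#' @return A [chromatogram()].
#' @export
read_chromatogram_csv <- function(path, sample_id = NA_character_,
                                  colony = NA_character_,
                                  source = NA_character_) {
  d <- utils::read.csv(path)
  if (!all(c("rt_min", "abundance") %in% names(d))) {
    stop("chromatogram CSV ", path, " needs columns rt_min, abundance")
  }
  chromatogram(d$rt_min, d$abundance, sample_id = sample_id, colony = colony,
               source = source)
}

#' Write a chromatogram sample CSV
#' @param chrom a [chromatogram()].
#' @param path output path.
#' @export
write_chromatogram_csv <- function(chrom, path) {
  utils::write.csv(data.frame(rt_min = chrom$rt, abundance = chrom$abundance),
                   path, row.names = FALSE)
}

#' Read a cohort manifest CSV
#'
#' Expected columns: `sample_id`, `colony`, `source`, `path`; optional
#' `n_ants`, `tf_volume_uL`. Paths are resolved relative to the manifest's
#' directory unless absolute.
#'
#' @param path manifest CSV path.
#' @return A list with `chromatograms` (named list) and `meta`.
#' @export
read_cohort_manifest <- function(path) {
  d <- utils::read.csv(path)
  need <- c("sample_id", "colony", "source", "path")
  if (!all(need %in% names(d))) {
    stop("manifest ", path, " needs columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(path)
  chroms <- lapply(seq_len(nrow(d)), function(i) {
    p <- d$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_chromatogram_csv(p, sample_id = d$sample_id[i], colony = d$colony[i],
                          source = d$source[i])
  })
  names(chroms) <- d$sample_id
  list(chromatograms = chroms, meta = d)
}

#' Read a spectral-count matrix CSV pair
#'
#' Counts CSV: columns `protein_id`, `length_aa`, then one column per
#' sample. Metadata CSV: columns `sample_id`, `condition`, `colony`.
#'
#' @param counts_path counts CSV path.
#' @param meta_path metadata CSV path (optional).
#' @return An [spc_matrix()].
#' @export
read_counts_csv <- function(counts_path, meta_path = NULL) {
  d <- utils::read.csv(counts_path, check.names = FALSE)
  need <- c("protein_id", "length_aa")
  if (!all(need %in% names(d))) {
    stop("counts CSV ", counts_path, " needs columns: ",
         paste(need, collapse = ", "))
  }
  counts <- as.matrix(d[, setdiff(names(d), need), drop = FALSE])
  rownames(counts) <- d$protein_id
  meta <- if (!is.null(meta_path)) utils::read.csv(meta_path) else NULL
  spc_matrix(counts, d$length_aa, meta)
}

#' Write a spectral-count matrix CSV pair
#' @param x an [spc_matrix()].
#' @param counts_path counts CSV path.
#' @param meta_path metadata CSV path (written when the matrix has
#'   metadata).
#' @export
write_counts_csv <- function(x, counts_path, meta_path = NULL) {
  d <- data.frame(protein_id = rownames(x$counts), length_aa = x$lengths,
                  x$counts, check.names = FALSE)
  utils::write.csv(d, counts_path, row.names = FALSE)
  if (!is.null(meta_path) && !is.null(x$meta)) {
    utils::write.csv(x$meta, meta_path, row.names = FALSE)
  }
  invisible(counts_path)
}
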