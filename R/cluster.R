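#' Agglomerative clustering with bootstrap edge support
#'
#' Clusters the columns of a feature matrix (bins x samples, or proteins x
#' samples) by correlation distance (`1 - r`) and average linkage, and
#' attaches per-edge support from bootstrap resampling of the feature rows:
#' each replicate resamples rows with replacement, rebuilds the tree, and an
#' edge's support is the percentage of replicates in which the same set of
#' leaves appears as a cluster. An approximately-unbiased (AU) correction by
#' multiscale bootstrap (resampling at several sample sizes and
#' extrapolating to infinite size via the signed-distance/curvature fit) is
#' available behind `multiscale = TRUE`.
#'
#' @param x numeric matrix, features in rows, samples in columns (>= 3
#'   columns). A list of `binned_profile` vectors is also accepted.
#' @param n_boot bootstrap replicates (default 10000).
#' @param multiscale compute AU support by multiscale bootstrap instead of
#'   plain bootstrap proportions.
#' @param scales relative resampling sizes for the multiscale route.
#' @param linkage agglomeration method for [stats::hclust()].
#' @return An object of class `boot_hclust`: `hclust` (the tree), `support`
#'   (percent support per internal node, in `merge` order), `n_boot`,
#'   `method`.
#' @export
hierarchical_cluster <- function(x, n_boot = 10000L, multiscale = FALSE,
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 linkage = "average") {
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    x <- do.call(cbind, lapply(x, as.numeric))
  }
  x <- as.matrix(x)
  if (ncol(x) < 3L) stop("need at least 3 profiles/samples to cluster")
  hc <- .cor_hclust(x, linkage)
  ref_clades <- .clades(hc)
  count_hits <- function(size) {
    hits <- numeric(length(ref_clades))
    for (b in seq_len(n_boot)) {
      rows <- sample.int(nrow(x), size, replace = TRUE)
      bx <- x[rows, , drop = FALSE]
      bh <- tryCatch(.cor_hclust(bx, linkage), error = function(e) NULL)
      if (is.null(bh)) next
      bc <- .clades(bh)
      hits <- hits + (ref_clades %in% bc)
    }
    hits / n_boot
  }
  if (!multiscale) {
    support <- 100 * count_hits(nrow(x))
    method <- "bootstrap"
  } else {
    sizes <- pmax(2L, round(scales * nrow(x)))
    bp <- vapply(sizes, count_hits, numeric(length(ref_clades)))
    support <- 100 * vapply(seq_along(ref_clades), function(i) {
      .au_probability(bp[i, ], sizes / nrow(x))
    }, numeric(1))
    method <- "multiscale (AU)"
  }
  structure(list(hclust = hc, support = support, n_boot = n_boot,
                 method = method, labels = colnames(x)),
            class = "boot_hclust")
}

.cor_hclust <- function(x, linkage) {
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0
  stats::hclust(stats::as.dist(1 - r), method = linkage)
}

# leaf sets under each internal node, as canonical strings in merge order
.clades <- function(hc) {
  n <- nrow(hc$merge)
  members <- vector("list", n)
  out <- character(n)
  labs <- hc$labels
  if (is.null(labs)) labs <- as.character(seq_len(n + 1L))
  for (i in seq_len(n)) {
    grab <- function(j) if (j < 0) labs[-j] else members[[j]]
    members[[i]] <- c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2]))
    out[i] <- paste(sort(members[[i]]), collapse = "\r")
  }
  out
}

# multiscale-bootstrap AU value: fit qnorm(1 - bp) = v * sqrt(r) + c / sqrt(r)
# over relative sizes r, then AU = 1 - pnorm(v - c)
.au_probability <- function(bp, r) {
  eps <- 0.5 / 10000
  bp <- pmin(pmax(bp, eps), 1 - eps)
  z <- stats::qnorm(1 - bp)
  sr <- sqrt(r)
  fit <- stats::lm(z ~ 0 + sr + I(1 / sr))
  v <- stats::coef(fit)[[1]]; cc <- stats::coef(fit)[[2]]
  1 - stats::pnorm(v - cc)
}

#' @export
print.boot_hclust <- function(x, ...) {
  cat(sprintf("<bootstrap clustering> %d leaves, %s support (%d replicates)\n",
              length(x$hclust$order), x$method, x$n_boot))
  cl <- .clades(x$hclust)
  for (i in seq_along(x$support)) {
    leaves <- strsplit(cl[i], "\r", fixed = TRUE)[[1]]
    cat(sprintf("  %3.0f%%  {%s}\n", x$support[i],
                paste(leaves, collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.boot_hclust <- function(x, ...) {
  graphics::plot(x$hclust, ...)
  invisible(x)
}

#' Export a clustering to Newick format
#'
#' Edge support values are written as internal node labels.
#'
#' @param x a [hierarchical_cluster()] result.
#' @param path output file; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "boot_hclust"))
  phy <- ape::as.phylo(x$hclust)
  # hclust merge order maps to phylo internal nodes through their clades
  cl <- .clades(x$hclust)
  phy$node.label <- rep("", phy$Nnode)
  for (i in seq_len(phy$Nnode)) {
    node <- ape::Ntip(phy) + i
    tips <- ape::extract.clade(phy, node)$tip.label
    key <- paste(sort(tips), collapse = "\r")
    j <- match(key, cl)
    if (!is.na(j)) phy$node.label[i] <- sprintf("%.0f", x$support[j])
  }
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
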