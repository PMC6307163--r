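#' Pairwise Euclidean distance matrix of feature vectors
#'
#' All-pairs Euclidean distances on the raw (unstandardized) vectors:
#' no feature scaling is applied by default, so the count and mean-position
#' blocks (magnitude ~10^2 for typical barcodes) dominate the metric, which
#' is the behaviour the downstream gap and tree analyses rely on. An
#' optional z-scaling flag exists for exploration.
#'
#' @param features Numeric matrix with at least two rows; rownames are the
#'   sequence ids.
#' @param scale Z-scale columns before computing distances (default off).
#' @return Symmetric numeric matrix with zero diagonal and ids as dimnames.
#' @export
distance_matrix <- function(features, scale = FALSE) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least two feature rows")
  bad <- which(apply(features, 1L, function(r) any(!is.finite(r))))
  if (length(bad) > 0L) {
    ids <- if (!is.null(rownames(features))) rownames(features)[bad] else bad
    stop("non-finite feature value(s) in row(s): ",
         paste(ids, collapse = ", "))
  }
  if (isTRUE(scale)) {
    features <- scale(features)
    features[, apply(is.na(features), 2L, any)] <- 0   # constant columns
  }
  as.matrix(stats::dist(features, method = "euclidean"))
}

#' Single-linkage dendrogram of a distance matrix
#'
#' Agglomerative clustering merging, at each step, the pair of clusters at
#' minimum single-link (nearest-member) distance. Returns the standard
#' `hclust` merge structure; single-linkage merge heights are
#' non-decreasing by construction and this is asserted on every run.
#'
#' @param D Symmetric distance matrix (or `dist` object) with ids as
#'   labels.
#' @return An `hclust` object (method `"single"`).
#' @export
single_linkage <- function(D) {
  d <- if (inherits(D, "dist")) D else stats::as.dist(D)
  if (attr(d, "Size") < 2L) stop("need at least two items")
  hc <- stats::hclust(d, method = "single")
  if (any(diff(hc$height) < -1e-9 * max(abs(hc$height), 1))) {
    stop("single-linkage heights not monotone; invalid distance input")
  }
  hc
}

#' Export a dendrogram as a Newick string
#'
#' With `branch_lengths = "height"` each branch gets half the difference
#' between parent and child merge heights (the usual ultrametric
#' convention for converting merge heights to branch lengths); with
#' `"none"` a cladogram without lengths is written. Duplicate leaf labels
#' are made unique by suffixing an index.
#'
#' @param tree An `hclust` object, e.g. from [single_linkage()].
#' @param branch_lengths `"height"` or `"none"`.
#' @return A single Newick string (terminated by `;`).
#' @examples
#' D <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' to_newick(single_linkage(D))  # "(a:1,b:1);"
#' @export
to_newick <- function(tree, branch_lengths = c("height", "none")) {
  branch_lengths <- match.arg(branch_lengths)
  stopifnot(inherits(tree, "hclust"))
  if (anyDuplicated(tree$labels)) {
    dup <- duplicated(tree$labels)
    tree$labels[dup] <- paste0(tree$labels[dup], "_", which(dup))
    message("duplicate leaf labels suffixed with index")
  }
  phy <- ape::as.phylo(tree)   # branch length = height difference / 2
  if (branch_lengths == "none") phy$edge.length <- NULL
  ape::write.tree(phy)
}

#' Barcode-gap analysis at a taxonomic rank
#'
#' Splits all pairwise Euclidean distances among the grouped items into
#' the within-group (intra) and between-group (inter) distributions and
#' reports their means: a usable barcode shows inter-group distances
#' clearly greater than intra-group ones. Inter-group distances are all
#' cross pairs (not centroid distances).
#'
#' @param features Numeric matrix of vectors, one row per sequence.
#' @param labels Group label per row at the chosen rank; rows with empty
#'   labels are excluded.
#' @param groups Optional subset of groups to restrict the analysis to.
#' @param bin_width Histogram bin width; default range/30.
#' @return Object of class `gap_report`: list with `intra`, `inter`
#'   (numeric distance vectors), `mean_intra`, `mean_inter` (`NA` when the
#'   corresponding list is empty), `ratio`, `n_groups`, and `histogram`
#'   (data frame `bin_start`, `bin_end`, `intra_count`, `inter_count`).
#' @export
barcode_gap <- function(features, labels, groups = NULL, bin_width = NULL) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  use <- nzchar(labels) & !is.na(labels)
  if (!is.null(groups)) use <- use & labels %in% groups
  features <- features[use, , drop = FALSE]
  labels <- labels[use]
  if (length(unique(labels)) < 1L || nrow(features) < 2L) {
    stop("need at least two grouped sequences")
  }
  D <- distance_matrix(features)
  lower <- lower.tri(D)
  same <- outer(labels, labels, `==`)
  intra <- D[lower & same]
  inter <- D[lower & !same]
  mean_intra <- if (length(intra)) mean(intra) else NA_real_
  mean_inter <- if (length(inter)) mean(inter) else NA_real_
  allv <- c(intra, inter)
  if (is.null(bin_width)) {
    bin_width <- max(allv) / 30
    if (bin_width == 0) bin_width <- 1
  }
  breaks <- seq(0, max(allv) + bin_width, by = bin_width)
  hist_df <- data.frame(
    bin_start = utils::head(breaks, -1),
    bin_end = utils::tail(breaks, -1),
    intra_count = if (length(intra))
      graphics::hist(intra, breaks = breaks, plot = FALSE)$counts
      else rep(0L, length(breaks) - 1L),
    inter_count = if (length(inter))
      graphics::hist(inter, breaks = breaks, plot = FALSE)$counts
      else rep(0L, length(breaks) - 1L))
  structure(list(intra = intra, inter = inter,
                 mean_intra = mean_intra, mean_inter = mean_inter,
                 ratio = if (!is.na(mean_intra) && mean_intra > 0)
                   mean_inter / mean_intra else NA_real_,
                 n_groups = length(unique(labels)),
                 bin_width = bin_width, histogram = hist_df),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("Barcode gap over", x$n_groups, "group(s)\n")
  cat("  intra pairs:", length(x$intra), " mean:",
      if (is.na(x$mean_intra)) "absent" else format(x$mean_intra,
                                                    digits = 5), "\n")
  cat("  inter pairs:", length(x$inter), " mean:",
      if (is.na(x$mean_inter)) "absent" else format(x$mean_inter,
                                                    digits = 5), "\n")
  if (!is.na(x$ratio)) cat("  inter/intra mean ratio:",
                           format(x$ratio, digits = 5), "\n")
  invisible(x)
}

#' @export
plot.gap_report <- function(x, ...) {
  h <- x$histogram
  ylim <- c(0, max(h$intra_count, h$inter_count))
  graphics::plot(h$bin_start, h$intra_count, type = "h", col = "darkgreen",
                 lwd = 3, ylim = ylim, xlab = "Euclidean distance",
                 ylab = "pair count", ...)
  graphics::lines(h$bin_start + x$bin_width / 3, h$inter_count,
                  type = "h", col = "steelblue", lwd = 3)
  graphics::legend("topright", legend = c("intra", "inter"),
                   col = c("darkgreen", "steelblue"), lwd = 3, bty = "n")
  invisible(x)
}

#' Serialize a gap report to JSON (and optionally its histogram to TSV)
#'
#' @param x A `gap_report`.
#' @param path JSON output path.
#' @param hist_path Optional TSV path for the histogram counts.
#' @return `path`, invisibly.
#' @export
write_gap_report <- function(x, path, hist_path = NULL) {
  stopifnot(inherits(x, "gap_report"))
  obj <- list(n_groups = x$n_groups,
              n_intra_pairs = length(x$intra),
              n_inter_pairs = length(x$inter),
              mean_intra = if (is.na(x$mean_intra)) NULL else x$mean_intra,
              mean_inter = if (is.na(x$mean_inter)) NULL else x$mean_inter,
              ratio = if (is.na(x$ratio)) NULL else x$ratio,
              bin_width = x$bin_width)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(hist_path)) {
    utils::write.table(x$histogram, hist_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
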