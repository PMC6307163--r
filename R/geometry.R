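#' Convex-hull disjointness of two point clouds
#'
#' Decides whether the convex hulls of two point sets P and Q in R^d are
#' disjoint by solving the feasibility system on convex combinations
#' sum_i lambda_i p_i = sum_j mu_j q_j with lambda, mu on their simplices
#' (lambda_i, mu_j >= 0 summing to 1). Rather than constructing either hull
#' explicitly, the slack of the equality system is minimized in the L2 norm
#' -- a convex quadratic program whose optimum is the distance between the
#' two hulls. The hulls intersect iff that distance is <= `tol`; in that
#' case the optimal (lambda, mu) is returned as a certificate and
#' re-verified by direct substitution before returning.
#'
#' @param P,Q Numeric matrices, one point per row, equal column counts.
#' @param tol Tolerance on the residual norm of the certificate.
#' @return An object of class `hull_test`: list with `disjoint` (logical),
#'   `distance` (minimum distance between the hulls), `certificate`
#'   (list `lambda`, `mu` when intersecting, else `NULL`) and `tol`.
#' @examples
#' P <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
#' hulls_disjoint(P, P + 10)$disjoint  # TRUE
#' @export
hulls_disjoint <- function(P, Q, tol = 1e-7) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) == 0L || nrow(Q) == 0L) stop("point sets must be nonempty")
  if (ncol(P) != ncol(Q)) {
    stop("dimension mismatch: ", ncol(P), " vs ", ncol(Q))
  }
  n <- nrow(P); m <- nrow(Q)
  M <- cbind(t(P), -t(Q))                      # d x (n + m)
  Dmat <- crossprod(M)
  scale <- mean(diag(Dmat)) + 1
  Amat <- cbind(c(rep(1, n), rep(0, m)),
                c(rep(0, n), rep(1, m)),
                diag(n + m))
  bvec <- c(1, 1, rep(0, n + m))
  sol <- NULL
  for (ridge in c(1e-10, 1e-8, 1e-6) * scale) {
    sol <- tryCatch(
      quadprog::solve.QP(Dmat + ridge * diag(n + m), rep(0, n + m),
                         Amat, bvec, meq = 2L),
      error = function(e) NULL)
    if (!is.null(sol)) break
  }
  if (is.null(sol)) {
    stop("quadratic program for the hull feasibility system failed")
  }
  x <- pmax(sol$solution, 0)
  lambda <- x[seq_len(n)]; mu <- x[n + seq_len(m)]
  lambda <- lambda / sum(lambda); mu <- mu / sum(mu)
  resid <- sqrt(sum((crossprod(P, lambda) - crossprod(Q, mu))^2))
  disjoint <- resid > tol
  cert <- NULL
  if (!disjoint) {
    # re-verify the certificate by direct substitution
    stopifnot(all(lambda >= 0), all(mu >= 0),
              abs(sum(lambda) - 1) < 1e-12, abs(sum(mu) - 1) < 1e-12,
              resid <= tol)
    cert <- list(lambda = lambda, mu = mu)
  }
  structure(list(disjoint = disjoint, distance = resid,
                 certificate = cert, tol = tol),
            class = "hull_test")
}

#' @export
print.hull_test <- function(x, ...) {
  cat("Convex hull feasibility test\n")
  cat("  verdict :", if (x$disjoint) "disjoint" else "intersecting", "\n")
  cat("  distance:", format(x$distance), " (tol ", format(x$tol), ")\n",
      sep = "")
  invisible(x)
}

#' Hull disjointness for every pair of labelled groups
#'
#' Runs [hulls_disjoint()] on the point clouds of every unordered pair of
#' group labels (or a supplied subset of pairs) and tallies intersections.
#'
#' @param features Numeric matrix, one point per row.
#' @param labels Group label per row.
#' @param pairs Optional two-column character matrix of group pairs to
#'   test; default all unordered pairs.
#' @param tol Passed to [hulls_disjoint()].
#' @return An object of class `hull_scan`: data frame with columns
#'   `group1`, `group2`, `disjoint`, `distance`, plus attribute
#'   `n_intersecting`.
#' @export
pairwise_hull_scan <- function(features, labels, pairs = NULL, tol = 1e-7) {
  stopifnot(nrow(features) == length(labels))
  groups <- sort(unique(as.character(labels)))
  if (length(groups) < 2L && is.null(pairs)) {
    out <- data.frame(group1 = character(), group2 = character(),
                      disjoint = logical(), distance = numeric())
    attr(out, "n_intersecting") <- 0L
    class(out) <- c("hull_scan", "data.frame")
    return(out)
  }
  if (is.null(pairs)) {
    pairs <- t(utils::combn(groups, 2L))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g1 <- pairs[i, 1L]; g2 <- pairs[i, 2L]
    ht <- hulls_disjoint(features[labels == g1, , drop = FALSE],
                         features[labels == g2, , drop = FALSE], tol = tol)
    data.frame(group1 = g1, group2 = g2, disjoint = ht$disjoint,
               distance = ht$distance, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_intersecting") <- sum(!out$disjoint)
  class(out) <- c("hull_scan", "data.frame")
  out
}

#' @export
print.hull_scan <- function(x, ...) {
  cat("Pairwise convex hull scan:", nrow(x), "pair(s),",
      attr(x, "n_intersecting"), "intersecting\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Linear discriminant projection of a feature matrix
#'
#' Classical multi-class discriminant analysis: the within-class scatter
#' S_w = sum_c sum_{x in c} (x - m_c)(x - m_c)^T and between-class scatter
#' S_b = sum_c n_c (m - m_c)(m - m_c)^T are formed and the projection W is
#' the top-d eigenvectors of S_w^{-1} S_b. With k classes at most k - 1
#' directions carry between-class signal; when two classes are projected to
#' two dimensions the single discriminant is augmented with the leading
#' within-class principal direction orthogonal to it (recorded in the
#' metadata) so a 2-D view always exists. A singular S_w triggers an
#' automatic ridge fallback with a warning.
#'
#' @param X Numeric matrix, one observation per row.
#' @param labels Class label per row (at least two classes).
#' @param d Target dimension, 1 or 2.
#' @return Object of class `lda_projection`: list with `W` (ncol(X) x d),
#'   `points` (data frame `id`, `label`, projected coordinates),
#'   `eigenvalues`, and `metadata`.
#' @export
lda_project <- function(X, labels, d = 2L) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels), d %in% c(1L, 2L))
  classes <- unique(labels)
  k <- length(classes)
  if (k < 2L) stop("need at least two classes")
  p <- ncol(X)
  m <- colMeans(X)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (cl in classes) {
    Xi <- X[labels == cl, , drop = FALSE]
    mi <- colMeans(Xi)
    Xc <- sweep(Xi, 2L, mi)
    Sw <- Sw + crossprod(Xc)
    Sb <- Sb + nrow(Xi) * tcrossprod(m - mi)
  }
  ridge_used <- FALSE
  Minv <- tryCatch(solve(Sw, Sb), error = function(e) NULL)
  if (is.null(Minv) || rcond(Sw) < 1e-12) {
    ridge <- 1e-6 * (mean(diag(Sw)) + 1)
    warning("within-class scatter singular or near-singular; ",
            "applying ridge ", format(ridge))
    ridge_used <- TRUE
    Minv <- solve(Sw + ridge * diag(p), Sb)
  }
  ee <- eigen(Minv)
  ev <- Re(ee$values)
  ord <- order(ev, decreasing = TRUE)
  n_disc <- min(d, k - 1L)
  W <- Re(ee$vectors[, ord[seq_len(n_disc)], drop = FALSE])
  augmented <- FALSE
  if (n_disc < d) {
    # two-class case projected to 2-D: add the leading within-class PC
    # orthogonal to the discriminant
    w1 <- W[, 1L] / sqrt(sum(W[, 1L]^2))
    proj <- diag(p) - tcrossprod(w1)
    pc <- eigen(proj %*% Sw %*% proj, symmetric = TRUE)$vectors[, 1L]
    W <- cbind(W, pc)
    augmented <- TRUE
  }
  # normalize and fix signs for determinism
  W <- apply(W, 2L, function(w) {
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) -w else w
  })
  Y <- X %*% W
  pts <- data.frame(id = if (!is.null(rownames(X))) rownames(X)
                    else as.character(seq_len(nrow(X))),
                    label = labels, stringsAsFactors = FALSE)
  pts$x <- Y[, 1L]
  if (d == 2L) pts$y <- Y[, 2L]
  structure(list(W = W, points = pts,
                 eigenvalues = ev[ord][seq_len(min(d, k - 1L))],
                 metadata = list(n_classes = k, d = d,
                                 ridge_used = ridge_used,
                                 augmented_with_pc = augmented)),
            class = "lda_projection")
}

#' @export
print.lda_projection <- function(x, ...) {
  cat("LDA projection to", x$metadata$d, "dimension(s),",
      x$metadata$n_classes, "classes\n")
  cat("  eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  if (x$metadata$augmented_with_pc) {
    cat("  second axis: leading within-class PC (two-class case)\n")
  }
  invisible(x)
}

#' @export
plot.lda_projection <- function(x, ...) {
  pts <- x$points
  cols <- as.integer(factor(pts$label))
  if (is.null(pts$y)) {
    graphics::stripchart(pts$x ~ factor(pts$label), method = "jitter",
                         pch = 19, col = unique(cols),
                         xlab = "LD1", ...)
  } else {
    graphics::plot(pts$x, pts$y, col = cols, pch = 19,
                   xlab = "LD1", ylab = "LD2", ...)
  }
  invisible(x)
}
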