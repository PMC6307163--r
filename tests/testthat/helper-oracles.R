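# Independent oracles used by the tests. Each is a deliberately naive
# implementation kept separate from the package code paths it checks.

# one-line loop evaluation of n_k, mu_k, D2_k
cmv_loop <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- c()
  for (i in seq_along(chars)) if (chars[i] == k) pos <- c(pos, i)
  if (length(pos) == 0) return(c(n = 0, mu = 0, d2 = 0))
  mu <- sum(pos) / length(pos)
  d2 <- 0
  for (p in pos) d2 <- d2 + (p - mu)^2
  c(n = length(pos), mu = mu, d2 = d2 / (length(pos) * nchar(seq)))
}

# brute-force subset average, centering on the FULL larger set's mean
# instead of each subset's own mean (the two must agree because the
# smaller set's deviations sum to zero)
brute_force_cov_fullmean <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  n <- length(a)
  ac <- a - mean(a)
  mub <- mean(b)
  subs <- utils::combn(b, n)
  mean(apply(subs, 2, function(s) sum(ac * (s - mub)) / n))
}

# random strictly-increasing position set
random_posset <- function(size, max_pos = 30) {
  sort(sample(max_pos, size))
}

# random ACGT sequence
random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# exact separating-axis verdict for the convex hulls of two 2-D point
# clouds; returns list(disjoint, margin) where margin > 0 is the best
# separation gap and margin <= 0 means no separating edge axis exists
polygons_disjoint_sat <- function(P, Q) {
  hull_edges <- function(X) {
    h <- X[grDevices::chull(X), , drop = FALSE]
    k <- nrow(h)
    if (k < 2) return(matrix(numeric(0), ncol = 2))
    e <- h[c(2:k, 1), , drop = FALSE] - h
    e[rowSums(e^2) > 0, , drop = FALSE]
  }
  axes <- rbind(hull_edges(P), hull_edges(Q))
  axes <- cbind(-axes[, 2], axes[, 1])            # edge normals
  axes <- axes / sqrt(rowSums(axes^2))
  best <- -Inf
  for (i in seq_len(nrow(axes))) {
    pp <- P %*% axes[i, ]
    qq <- Q %*% axes[i, ]
    gap <- max(min(qq) - max(pp), min(pp) - max(qq))
    best <- max(best, gap)
  }
  list(disjoint = best > 0, margin = best)
}

# naive O(n^3) single-linkage agglomeration; returns merge heights in
# merge order, ties broken by the lexicographically smallest cluster pair
single_linkage_naive <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- min(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    heights <- c(heights, best[1])
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  heights
}

# compact synthetic dataset for fast module-level tests
tiny_dataset <- function(seed = 1, n_species = 6, specimens = c(3L, 5L),
                         root_length = c(140L, 160L)) {
  generate_dataset(synthetic_spec(
    n_classes = 2L, orders_per_class = 1L, families_per_order = 1L,
    genera_per_family = 2L, n_species = n_species,
    specimens_per_species = specimens, root_length = root_length,
    seed = seed))
}

# the full study-condition benchmark: features + records
benchmark_run <- function(seed) {
  ds <- generate_dataset(synthetic_spec(seed = seed))
  list(records = ds$records, X = featurize(ds$records, "nv18"))
}
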