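#' Positions of a nucleotide within a sequence
#'
#' Returns the 1-based positions at which nucleotide `k` occurs, in
#' ascending order. The size of the returned set is the count feature
#' n_k of the natural vector.
#'
#' @param seq Validated sequence string over \{A, C, G, T\}.
#' @param k One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return Integer vector of positions (possibly empty).
#' @examples
#' positions_of("ACGTAC", "A")  # 1, 5
#' @export
positions_of <- function(seq, k) {
  stopifnot(k %in% c("A", "C", "G", "T"))
  which(strsplit(seq, "", fixed = TRUE)[[1L]] == k)
}

#' Count, mean position and normalized positional variation per nucleotide
#'
#' For each nucleotide k in a sequence of length N computes the count
#' n_k, the mean position mu_k, and the normalized variation
#' D2_k = sum_i (i - mu_k)^2 / (n_k * N) over the positions i at which k
#' occurs. An absent nucleotide yields (0, 0, 0) by convention so that
#' vectors remain finite and comparable.
#'
#' @inheritParams positions_of
#' @return A 4 x 3 numeric matrix with rows `A, C, G, T` and columns
#'   `n`, `mu`, `d2`.
#' @examples
#' count_mean_var("ACGTAC")["A", ]  # n 2, mu 3, d2 2/3
#' @export
count_mean_var <- function(seq) {
  N <- nchar(seq)
  stopifnot(N >= 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  out <- matrix(0, nrow = 4L, ncol = 3L,
                dimnames = list(c("A", "C", "G", "T"), c("n", "mu", "d2")))
  for (k in rownames(out)) {
    pos <- which(chars == k)
    nk <- length(pos)
    if (nk == 0L) next
    mu <- mean(pos)
    out[k, ] <- c(nk, mu, sum((pos - mu)^2) / (nk * N))
  }
  out
}

#' Subset-averaged covariance of two position sets (brute force)
#'
#' Literal evaluation of the defining average: for ascending position sets
#' A (size n) and B (size m) with m >= n (arguments are swapped if needed),
#' every size-n subset of B is taken in ascending order, the covariance
#' sum_i (a_i - mu_A)(b_i - mu_B)/n is computed with each set's own mean,
#' and the C(m, n) results are averaged. Exponential in set size; this is
#' the test oracle, the production path is [subset_avg_cov()].
#'
#' @param a,b Strictly increasing numeric vectors (position sets).
#' @param max_subsets Guard on the number of enumerated subsets.
#' @return The averaged covariance (symmetric in `a`, `b`).
#' @examples
#' brute_force_cov(c(1, 2), c(3, 4, 5))  # 1/3
#' @export
brute_force_cov <- function(a, b, max_subsets = 1e6) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  n <- length(a); m <- length(b)
  if (choose(m, n) > max_subsets) {
    stop("C(", m, ", ", n, ") subsets exceed the enumeration guard; ",
         "use subset_avg_cov()")
  }
  ac <- a - mean(a)
  subs <- utils::combn(b, n)
  vals <- apply(subs, 2L, function(s) sum(ac * (s - mean(s))) / n)
  mean(vals)
}

#' Subset-averaged covariance of two position sets (closed form)
#'
#' Computes the same quantity as [brute_force_cov()] in O(n * m): because
#' the smaller set's deviations sum to zero, each subset's own mean cancels
#' from the average, which collapses to
#' (1/n) * sum_j b_j * sum_i (a_i - mu_A) * P(rank of b_j in the subset = i)
#' with hypergeometric rank weights
#' P = C(j-1, i-1) * C(m-j, n-i) / C(m, n).
#'
#' @inheritParams brute_force_cov
#' @return The averaged covariance, equal to `brute_force_cov(a, b)` up to
#'   floating-point error.
#' @export
subset_avg_cov <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("position sets must be nonempty")
  }
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  n <- length(a); m <- length(b)
  ac <- a - mean(a)
  if (n == m) {
    return(sum(ac * (b - mean(b))) / n)
  }
  i <- seq_len(n); j <- seq_len(m)
  # W[i, j] = P(j-th smallest of B occupies slot i of an ascending subset)
  logw <- outer(i - 1, j - 1, function(ii, jj) lchoose(jj, ii)) +
    outer(n - i, m - j, function(ni, mj) lchoose(mj, ni)) -
    lchoose(m, n)
  W <- exp(logw)
  W[is.nan(W) | logw == -Inf] <- 0
  drop(crossprod(ac, W %*% b)) / n
}

#' Covariance feature of a nucleotide pair
#'
#' The covariance entry of the 18-dimensional natural vector:
#' `Cov(k1, k2) = Cov(A, B) / N` where A and B are the position sets of the
#' two nucleotides, Cov(A, B) is the subset-averaged covariance, and N is
#' the sequence length. If either nucleotide is absent the feature is 0 by
#' convention. For `k1 == k2` the definition reduces exactly to the
#' normalized variation D2_k.
#'
#' @inheritParams positions_of
#' @param k1,k2 Nucleotides, each one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return A single numeric value.
#' @examples
#' cov_pair("ACGTAC", "A", "C")  # 2/3
#' @export
cov_pair <- function(seq, k1, k2) {
  N <- nchar(seq)
  A <- positions_of(seq, k1)
  B <- positions_of(seq, k2)
  if (length(A) == 0L || length(B) == 0L) return(0)
  subset_avg_cov(A, B) / N
}

.nv18_names <- c("n_A", "n_C", "n_G", "n_T",
                 "mu_A", "mu_C", "mu_G", "mu_T",
                 "d2_A", "d2_C", "d2_G", "d2_T",
                 "cov_AC", "cov_AG", "cov_AT",
                 "cov_CG", "cov_CT", "cov_GT")

.nv_pairs <- list(c("A", "C"), c("A", "G"), c("A", "T"),
                  c("C", "G"), c("C", "T"), c("G", "T"))

#' The 18-dimensional natural vector of a sequence
#'
#' Maps a sequence to the ordered features
#' (n_A, n_C, n_G, n_T, mu_A, ..., mu_T, D2_A, ..., D2_T,
#' Cov(A,C)/N, Cov(A,G)/N, Cov(A,T)/N, Cov(C,G)/N, Cov(C,T)/N, Cov(G,T)/N).
#' The first four entries sum to the sequence length; the covariance block
#' uses the subset-averaged covariance divided by N exactly once, matching
#' the worked value Cov(A,C) = 2/3 for the sequence `ACGTAC`.
#'
#' @inheritParams positions_of
#' @return Named numeric vector of length 18.
#' @examples
#' natural_vector18("ACGTAC")
#' @export
natural_vector18 <- function(seq) {
  cmv <- count_mean_var(seq)
  N <- nchar(seq)
  pos <- lapply(c(A = "A", C = "C", G = "G", T = "T"),
                function(k) positions_of(seq, k))
  covs <- vapply(.nv_pairs, function(p) {
    A <- pos[[p[1L]]]; B <- pos[[p[2L]]]
    if (length(A) == 0L || length(B) == 0L) 0 else subset_avg_cov(A, B) / N
  }, numeric(1))
  stats::setNames(c(cmv[, "n"], cmv[, "mu"], cmv[, "d2"], covs), .nv18_names)
}

#' The 12-dimensional natural vector (no covariance block)
#'
#' @inheritParams positions_of
#' @return Named numeric vector of length 12: the count, mean-position and
#'   normalized-variation blocks of [natural_vector18()].
#' @export
natural_vector12 <- function(seq) {
  cmv <- count_mean_var(seq)
  stats::setNames(c(cmv[, "n"], cmv[, "mu"], cmv[, "d2"]), .nv18_names[1:12])
}

#' Natural vector with one feature block removed
#'
#' Ablation variants used to gauge the contribution of each feature family:
#' dropping `number`, `mean_position` or `normalized_variation` leaves a
#' 14-dimensional vector; dropping `covariance` leaves the 12-dimensional
#' natural vector.
#'
#' @inheritParams positions_of
#' @param drop One of `"number"`, `"mean_position"`,
#'   `"normalized_variation"`, `"covariance"`.
#' @return Named numeric vector of length 14 or 12 with the remaining
#'   blocks in their original order.
#' @export
ablated_vector <- function(seq, drop = c("number", "mean_position",
                                         "normalized_variation",
                                         "covariance")) {
  drop <- match.arg(drop)
  v <- natural_vector18(seq)
  idx <- switch(drop,
                number = 1:4,
                mean_position = 5:8,
                normalized_variation = 9:12,
                covariance = 13:18)
  v[-idx]
}

#' Overlapping k-mer count vector
#'
#' Counts every overlapping k-mer of the sequence over the alphabet
#' \{A, C, G, T\} in lexicographic order; the counts sum to N - k + 1.
#' The k = 5 setting is the conventional baseline this representation is
#' compared against.
#'
#' @inheritParams positions_of
#' @param k Word size (>= 1); the sequence must be at least k long.
#' @param normalize Divide counts by N - k + 1 to give frequencies.
#' @return Named numeric vector of length 4^k.
#' @export
kmer_vector <- function(seq, k = 5L, normalize = FALSE) {
  stopifnot(k >= 1L)
  if (nchar(seq) < k) {
    stop("sequence of length ", nchar(seq), " is shorter than k = ", k)
  }
  cnt <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                              width = k)
  if (normalize) cnt <- cnt / (nchar(seq) - k + 1)
  cnt
}

#' Feature matrix for a set of barcode records
#'
#' Applies one vectorizer to every record. `method` is one of `"nv18"`,
#' `"nv12"`, `"ablated:<block>"` (block as in [ablated_vector()]) or
#' `"kmer:<k>"`. Deterministic: identical sequences yield identical rows.
#'
#' @param records Data frame with columns `id` and `seq` (validated).
#' @param method Vectorizer specification string.
#' @return Numeric matrix, one row per record (rownames = ids), named
#'   feature columns.
#' @examples
#' recs <- data.frame(id = "x", seq = "ACGTAC")
#' featurize(recs, "nv18")
#' @export
featurize <- function(records, method = "nv18") {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  fn <- if (method == "nv18") {
    natural_vector18
  } else if (method == "nv12") {
    natural_vector12
  } else if (startsWith(method, "ablated:")) {
    block <- sub("^ablated:", "", method)
    function(s) ablated_vector(s, drop = block)
  } else if (startsWith(method, "kmer:")) {
    k <- as.integer(sub("^kmer:", "", method))
    if (is.na(k)) stop("bad k-mer size in method '", method, "'")
    function(s) kmer_vector(s, k = k)
  } else {
    stop("unknown featurization method '", method, "'")
  }
  if (nrow(records) == 0L) {
    ncols <- if (method == "nv18") 18L else if (method == "nv12") 12L else 0L
    return(matrix(numeric(0), nrow = 0L, ncol = ncols,
                  dimnames = list(NULL, if (ncols == 18L) .nv18_names
                                  else if (ncols == 12L) .nv18_names[1:12])))
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    tryCatch(fn(records$seq[i]), error = function(e) {
      stop("record '", records$id[i], "': ", conditionMessage(e),
           call. = FALSE)
    })
  })
  X <- do.call(rbind, rows)
  rownames(X) <- records$id
  X
}

#' Write a feature matrix as TSV
#'
#' @param X Feature matrix from [featurize()].
#' @param path Output path; the first column `id` holds the rownames.
#' @return `path`, invisibly.
#' @export
write_features <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#' @param path TSV path with an `id` column.
#' @return Numeric matrix with ids as rownames.
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  X <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  rownames(X) <- df$id
  X
}
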