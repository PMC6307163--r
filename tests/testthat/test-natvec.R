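test_that("nucleotide position sets match the worked example", {
  expect_equal(positions_of("ACGTAC", "A"), c(1L, 5L))
  expect_equal(positions_of("ACGTAC", "C"), c(2L, 6L))
  expect_equal(positions_of("AAAA", "T"), integer(0))
  expect_error(positions_of("ACGT", "N"))
})

test_that("count/mean/variation features match loop-oracle values", {
  cmv <- count_mean_var("ACGTAC")
  expect_equal(cmv["A", "mu"], 3)
  expect_equal(cmv["C", "mu"], 4)
  expect_equal(cmv["A", "d2"], 2 / 3)      # ((1-3)^2 + (5-3)^2) / (2*6)
  cmv4 <- count_mean_var("AAAA")
  expect_equal(unname(cmv4["A", ]), c(4, 2.5, 5 / 16))
  expect_equal(unname(cmv4["G", ]), c(0, 0, 0))   # absent-base convention
  set.seed(42)
  for (i in 1:20) {
    s <- random_seq(sample(5:60, 1))
    cmv <- count_mean_var(s)
    for (k in c("A", "C", "G", "T")) {
      expect_equal(unname(cmv[k, ]), unname(cmv_loop(s, k)))
    }
    expect_equal(sum(cmv[, "n"]), nchar(s))   # counts conserve length
  }
})

test_that("brute-force subset covariance reproduces hand-derived cases", {
  expect_equal(brute_force_cov(c(1, 5), c(2, 6)), 4)     # equal-size case
  expect_equal(brute_force_cov(c(1, 2), c(3, 4, 5)), 1 / 3)
  expect_equal(brute_force_cov(3, c(1, 9)), 0)   # singleton deviations vanish
  expect_error(brute_force_cov(1:20, 1:40, max_subsets = 100),
               "enumeration guard")
})

test_that("closed-form covariance equals brute force, both centerings", {
  set.seed(99)
  for (i in 1:60) {
    a <- random_posset(sample(1:6, 1))
    b <- random_posset(sample(1:6, 1))
    bf <- brute_force_cov(a, b)
    expect_equal(subset_avg_cov(a, b), bf, tolerance = 1e-9)
    # each subset's own mean vs the full larger-set mean: identical
    expect_equal(brute_force_cov_fullmean(a, b), bf, tolerance = 1e-12)
  }
})

test_that("subset covariance is symmetric, translation and scale covariant", {
  set.seed(7)
  for (i in 1:20) {
    a <- random_posset(sample(2:6, 1), 40)
    b <- random_posset(sample(2:6, 1), 40)
    v <- subset_avg_cov(a, b)
    expect_equal(subset_avg_cov(b, a), v)
    expect_equal(subset_avg_cov(a + 11, b + 11), v, tolerance = 1e-9)
    expect_equal(subset_avg_cov(3 * a, 3 * b), 9 * v, tolerance = 1e-9)
  }
  expect_equal(subset_avg_cov(3, c(1, 9)), 0)
  expect_error(subset_avg_cov(numeric(0), 1:3), "nonempty")
})

test_that("pairwise covariance feature matches the printed worked value", {
  expect_equal(cov_pair("ACGTAC", "A", "C"), 2 / 3)
  expect_equal(cov_pair("ACGTAC", "A", "A"), 2 / 3)   # equals D2_A
  expect_equal(cov_pair("ACGTAC", "A", "G"), 0)       # singleton partner
  expect_equal(cov_pair("AAAA", "A", "T"), 0)         # absent partner
})

test_that("self-covariance equals the normalized variation identically", {
  set.seed(13)
  for (i in 1:25) {
    s <- random_seq(sample(8:50, 1))
    cmv <- count_mean_var(s)
    for (k in c("A", "C", "G", "T")) {
      if (cmv[k, "n"] >= 1) {
        expect_equal(cov_pair(s, k, k), unname(cmv[k, "d2"]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the 18-dimensional vector assembles in the documented order", {
  v <- natural_vector18("ACGTAC")
  expect_equal(names(v),
               c("n_A", "n_C", "n_G", "n_T", "mu_A", "mu_C", "mu_G", "mu_T",
                 "d2_A", "d2_C", "d2_G", "d2_T", "cov_AC", "cov_AG",
                 "cov_AT", "cov_CG", "cov_CT", "cov_GT"))
  expect_equal(unname(v),
               c(2, 2, 1, 1, 3, 4, 3, 4, 2/3, 2/3, 0, 0, 2/3, 0, 0, 0, 0, 0))
  expect_equal(unname(natural_vector18("A")),
               c(1, rep(0, 3), 1, rep(0, 13)))
  set.seed(3)
  for (i in 1:10) {
    s <- random_seq(sample(4:80, 1))
    expect_equal(sum(natural_vector18(s)[1:4]), nchar(s))
  }
})

test_that("12-dim and ablated variants drop the right blocks", {
  v18 <- natural_vector18("ACGTAC")
  expect_equal(natural_vector12("ACGTAC"), v18[1:12])
  expect_equal(unname(natural_vector12("AAAA")),
               c(4, 0, 0, 0, 2.5, 0, 0, 0, 5/16, 0, 0, 0))
  expect_equal(ablated_vector("ACGTAC", "covariance"),
               natural_vector12("ACGTAC"))
  vn <- ablated_vector("ACGTAC", "number")
  expect_length(vn, 14)
  expect_equal(unname(vn[1:4]), c(3, 4, 3, 4))
  vm <- ablated_vector("ACGTAC", "mean_position")
  expect_equal(names(vm)[1:5], c("n_A", "n_C", "n_G", "n_T", "d2_A"))
  expect_length(ablated_vector("ACGTAC", "normalized_variation"), 14)
  expect_error(ablated_vector("ACGTAC", "bogus"))
})

test_that("k-mer counts are lexicographic and conserve window count", {
  k1 <- kmer_vector("ACGTAC", 1)
  expect_equal(unname(k1), c(2, 2, 1, 1))
  k2 <- kmer_vector("AAAA", 2)
  expect_equal(unname(k2["AA"]), 3)
  expect_equal(sum(k2), 3)
  expect_equal(names(k2)[1:4], c("AA", "AC", "AG", "AT"))
  set.seed(8)
  s <- random_seq(100)
  expect_equal(sum(kmer_vector(s, 5)), 96)
  expect_length(kmer_vector(s, 5), 4^5)
  expect_equal(sum(kmer_vector(s, 5, normalize = TRUE)), 1)
  expect_error(kmer_vector("ACG", 5), "shorter")
})

test_that("featurize is deterministic, shape-correct and id-annotated", {
  recs <- data.frame(id = c("a", "b", "c"),
                     seq = c("ACGTAC", "ACGTAC", "GGTTAA"))
  X <- featurize(recs, "nv18")
  expect_equal(dim(X), c(3L, 18L))
  expect_equal(rownames(X), c("a", "b", "c"))
  expect_equal(X["a", ], X["b", ])           # same sequence, same row
  expect_identical(X, featurize(recs, "nv18"))
  expect_equal(dim(featurize(recs, "nv12")), c(3L, 12L))
  expect_equal(dim(featurize(recs, "ablated:number")), c(3L, 14L))
  expect_equal(dim(featurize(recs, "kmer:2")), c(3L, 16L))
  empty <- featurize(recs[0, ], "nv18")
  expect_equal(dim(empty), c(0L, 18L))
  expect_error(featurize(recs, "nosuch"), "unknown")
  recs$seq[2] <- "AC"
  expect_error(featurize(recs, "kmer:5"), "'b'")
})

test_that("feature matrices round-trip through TSV", {
  ds <- tiny_dataset(seed = 4)
  X <- featurize(ds$records, "nv18")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_features(X, tsv)
  expect_equal(read_features(tsv), X, tolerance = 1e-12)
})
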