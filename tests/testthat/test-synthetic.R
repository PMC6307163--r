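test_that("spec validation rejects impossible settings", {
  expect_error(synthetic_spec(n_species = 0), "n_species")
  expect_error(synthetic_spec(rates = list(class = 0.01, order = 0.2,
                                           family = 0.1, genus = 0.05,
                                           species = 0.02,
                                           specimen = 0.001)),
               "non-increasing")
  expect_error(synthetic_spec(rates = list(class = 0.2, order = 0.1,
                                           family = 0.05, genus = 0.02,
                                           species = 0.01)),
               "specimen")
  # more genera than species cannot be populated
  sp <- synthetic_spec(n_classes = 4, orders_per_class = 2,
                       families_per_order = 2, genera_per_family = 2,
                       n_species = 10)
  expect_error(generate_dataset(sp), "smaller than")
})

test_that("zero-rate spec degenerates to identical specimens per species", {
  sp <- synthetic_spec(n_classes = 1, orders_per_class = 1,
                       families_per_order = 1, genera_per_family = 1,
                       n_species = 2, specimens_per_species = 5L,
                       root_length = 100L,
                       rates = list(class = 0, order = 0, family = 0,
                                    genus = 0, species = 0, specimen = 0),
                       seed = 2)
  ds <- generate_dataset(sp)
  expect_equal(nrow(ds$records), 10L)
  for (s in unique(ds$records$species)) {
    expect_length(unique(ds$records$seq[ds$records$species == s]), 1L)
  }
  # all-zero rates: even the two species coincide, intra distances all 0
  X <- featurize(ds$records, "nv18")
  gr <- barcode_gap(X, ds$records$species)
  expect_equal(gr$intra, rep(0, length(gr$intra)))
})

test_that("generation is deterministic and hierarchically labelled", {
  sp <- synthetic_spec(seed = 11)
  d1 <- generate_dataset(sp)
  d2 <- generate_dataset(sp)
  expect_identical(d1$records, d2$records)

  expect_equal(length(unique(d1$records$species)), 30L)
  expect_equal(length(unique(d1$records$class)), 2L)
  expect_equal(length(unique(d1$records$genus)), 16L)
  cnt <- table(d1$records$species)
  expect_true(all(cnt >= 5 & cnt <= 20))
  lens <- nchar(d1$records$seq)
  expect_true(all(lens >= 500 & lens <= 800))
  # each species maps to exactly one genus/family/order/class lineage
  lin <- unique(d1$records[, c("class", "order", "family", "genus",
                               "species")])
  expect_equal(nrow(lin), 30L)

  # byte-identical FASTA on re-generation
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  t1 <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(d1, f1, t1)
  write_dataset(generate_dataset(sp), f2, withr::local_tempfile())
  expect_identical(readLines(f1), readLines(f2))

  # outputs are consumable by the sequences module unchanged
  back <- attach_taxonomy(read_fasta(f1), read_taxonomy(t1))
  expect_equal(back$species, d1$records$species)
  expect_equal(nrow(filter_dataset(back, TRUE, 2)$removed), 0L)
})

test_that("raising the within-species rate raises intra distances", {
  rates_grid <- c(0.001, 0.005, 0.02, 0.05)
  mean_intra <- sapply(rates_grid, function(r) {
    m <- sapply(1:3, function(s) {
      sp <- synthetic_spec(n_classes = 1, orders_per_class = 1,
                           families_per_order = 1, genera_per_family = 2,
                           n_species = 4, specimens_per_species = 5L,
                           root_length = 300L,
                           rates = list(class = 0.25, order = 0.2,
                                        family = 0.15, genus = 0.1,
                                        species = 0.05, specimen = r),
                           seed = 100 + s)
      ds <- generate_dataset(sp)
      barcode_gap(featurize(ds$records, "nv18"),
                  ds$records$species)$mean_intra
    })
    mean(m)
  })
  expect_gt(stats::cor(rates_grid, mean_intra, method = "spearman"), 0)
  expect_true(all(diff(mean_intra) > 0))
})

test_that("indel events change sequence lengths when enabled", {
  sp <- synthetic_spec(n_classes = 1, orders_per_class = 1,
                       families_per_order = 1, genera_per_family = 1,
                       n_species = 2, specimens_per_species = 10L,
                       root_length = 200L, indel_rate = 0.02, seed = 6)
  ds <- generate_dataset(sp)
  expect_gt(length(unique(nchar(ds$records$seq))), 1L)
})

test_that("outlier spiking lengthens and GC-shifts the flagged records", {
  ds <- tiny_dataset(seed = 41, n_species = 4, specimens = c(6L, 8L))
  set.seed(41)
  spiked <- spike_outliers(ds, n = 2, length_delta = 120, gc_delta = 0.05)
  ids <- attr(spiked, "outlier_ids")
  expect_length(ids, 2L)
  expect_true(all(spiked$truth$outlier[spiked$truth$id %in% ids]))

  st_old <- seq_stats(ds$records)
  st_new <- seq_stats(spiked$records)
  for (id in ids) {
    expect_gte(st_new$length[st_new$id == id],
               st_old$length[st_old$id == id] + 120)
    expect_gt(st_new$gc_fraction[st_new$id == id],
              st_old$gc_fraction[st_old$id == id] + 0.03)
  }
  # untouched records unchanged
  other <- setdiff(ds$records$id, ids)
  expect_equal(spiked$records$seq[spiked$records$id %in% other],
               ds$records$seq[ds$records$id %in% other])

  expect_identical(spike_outliers(ds, n = 0), ds)
  expect_error(spike_outliers(ds, species = ds$records$species[1], n = 100),
               "only")
  expect_error(spike_outliers(ds, n = 1, gc_delta = 0.9), "outside")
})

test_that("spiked outliers attach basally to their species clade", {
  basal <- sapply(1:8, function(s) {
    ds <- tiny_dataset(seed = 500 + s, n_species = 4, specimens = 8L)
    target <- names(which.max(table(ds$records$species)))
    set.seed(500 + s)
    spiked <- spike_outliers(ds, species = target, n = 1,
                             length_delta = 120, gc_delta = 0.05)
    out_id <- attr(spiked, "outlier_ids")
    keep <- spiked$records$species == target
    X <- featurize(spiked$records[keep, ], "nv18")
    hc <- single_linkage(distance_matrix(X))
    # the outlier joins its species cluster last iff it appears in the
    # final merge row of the species subtree
    last <- hc$merge[nrow(hc$merge), ]
    singletons <- -last[last < 0]
    out_idx <- which(spiked$records$id[keep] == out_id)
    out_idx %in% singletons
  })
  expect_gte(mean(basal), 0.5)
})
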