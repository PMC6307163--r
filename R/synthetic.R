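#' Specification for a synthetic hierarchical barcode dataset
#'
#' Describes a five-rank taxonomy (class > order > family > genus >
#' species) of ancestral sequences and the per-rank substitution rates
#' used to derive each child ancestor from its parent, plus the
#' within-species rate applied to each specimen. The defaults describe a
#' compact benchmark emulating the structure of curated fungal ITS
#' barcode sets: 30 species under a 2 x 2 x 2 x 2 upper hierarchy,
#' 5-20 specimens per species (uneven sizes), root sequences of
#' 500-800 bp (the standard short-fragment barcode length), 0.5%
#' within-species divergence and 5% between sibling species, with
#' divergence growing monotonically toward the deeper ranks.
#'
#' @param n_classes Number of classes.
#' @param orders_per_class,families_per_order,genera_per_family Children
#'   per parent at each rank; a scalar or a `c(min, max)` range.
#' @param n_species Total number of species, distributed across genera
#'   (each genus gets at least one).
#' @param specimens_per_species Scalar or `c(min, max)` range.
#' @param root_length Scalar or `c(min, max)` range in bp.
#' @param rates Named list of per-rank substitution probabilities per
#'   site: `class`, `order`, `family`, `genus`, `species` (ancestor
#'   derivation) and `specimen` (within-species).
#' @param indel_rate Per-site probability of an indel event when deriving
#'   a specimen (default 0: substitutions only).
#' @param indel_length `c(min, max)` indel length in bp.
#' @param base_freqs Root base composition (named, sums to 1).
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 2L,
                           orders_per_class = 2L,
                           families_per_order = 2L,
                           genera_per_family = 2L,
                           n_species = 30L,
                           specimens_per_species = c(5L, 20L),
                           root_length = c(500L, 800L),
                           rates = list(class = 0.25, order = 0.20,
                                        family = 0.15, genus = 0.10,
                                        species = 0.05, specimen = 0.005),
                           indel_rate = 0,
                           indel_length = c(1L, 5L),
                           base_freqs = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           seed = 1L) {
  stopifnot(n_classes >= 1L, n_species >= 1L,
            all(unlist(rates) >= 0), all(unlist(rates) < 1),
            indel_rate >= 0, indel_rate < 1,
            abs(sum(base_freqs) - 1) < 1e-8)
  need <- c("class", "order", "family", "genus", "species", "specimen")
  miss <- setdiff(need, names(rates))
  if (length(miss)) stop("rates lacks: ", paste(miss, collapse = ", "))
  # divergence should not shrink toward the root
  rr <- unlist(rates[need])
  if (any(diff(rr) > 0)) {
    stop("per-rank rates must be non-increasing from class to specimen")
  }
  structure(list(n_classes = n_classes,
                 orders_per_class = orders_per_class,
                 families_per_order = families_per_order,
                 genera_per_family = genera_per_family,
                 n_species = n_species,
                 specimens_per_species = specimens_per_species,
                 root_length = root_length,
                 rates = rates,
                 indel_rate = indel_rate,
                 indel_length = indel_length,
                 base_freqs = base_freqs,
                 seed = seed),
            class = "synthetic_spec")
}

# sample an integer from a scalar or a c(min, max) range
.rint <- function(r) {
  if (length(r) == 1L) as.integer(r)
  else sample(seq(r[1L], r[2L]), 1L)
}

.bases <- c("A", "C", "G", "T")

# substitute each site independently with probability `rate` to one of
# the three other bases (Jukes-Cantor-like uniform substitution)
.mutate <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(.bases, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  chars
}

# apply random insertion/deletion events
.indel <- function(chars, rate, len_range) {
  if (rate <= 0) return(chars)
  n_events <- stats::rbinom(1L, length(chars), rate)
  for (e in seq_len(n_events)) {
    L <- .rint(len_range)
    if (stats::runif(1) < 0.5 && length(chars) > L + 1L) {   # deletion
      at <- sample(length(chars) - L, 1L)
      chars <- chars[-(at:(at + L - 1L))]
    } else {                                                  # insertion
      at <- sample(length(chars), 1L)
      ins <- sample(.bases, L, replace = TRUE)
      chars <- append(chars, ins, after = at)
    }
  }
  chars
}

# split `total` into `parts` positive integers, uneven, deterministic
# given the RNG state
.partition_total <- function(total, parts) {
  stopifnot(total >= parts)
  cuts <- sort(sample(total - 1L, parts - 1L))
  diff(c(0L, cuts, total))
}

#' Generate a hierarchically structured synthetic barcode dataset
#'
#' Simulates one root sequence, derives an ancestor per taxon down the
#' five ranks by applying the per-rank substitution rate of the spec, and
#' emits each specimen as its species ancestor with within-species
#' mutations (and optional indels). All randomness is fixed by
#' `spec$seed`, so a given spec is byte-reproducible.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `records` (data frame `id`, `seq`, `class`,
#'   `order`, `family`, `genus`, `species`) and `truth` (the taxonomy
#'   plus an `outlier` flag column, with the generating spec attached as
#'   attribute `"spec"`).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  root_len <- .rint(spec$root_length)
  root <- sample(.bases, root_len, replace = TRUE,
                 prob = spec$base_freqs[.bases])
  # enumerate genera with their lineage
  lineage <- list()
  oi <- fi <- gi <- 0L
  for (ci in seq_len(spec$n_classes)) {
    cl_anc <- .mutate(root, spec$rates$class)
    cl_name <- sprintf("Class%02d", ci)
    for (o in seq_len(.rint(spec$orders_per_class))) {
      oi <- oi + 1L
      or_anc <- .mutate(cl_anc, spec$rates$order)
      or_name <- sprintf("Order%02d", oi)
      for (f in seq_len(.rint(spec$families_per_order))) {
        fi <- fi + 1L
        fa_anc <- .mutate(or_anc, spec$rates$family)
        fa_name <- sprintf("Family%02d", fi)
        for (g in seq_len(.rint(spec$genera_per_family))) {
          gi <- gi + 1L
          lineage[[gi]] <- list(class = cl_name, order = or_name,
                                family = fa_name,
                                genus = sprintf("Genus%02d", gi),
                                anc = .mutate(fa_anc, spec$rates$genus))
        }
      }
    }
  }
  n_genera <- length(lineage)
  if (spec$n_species < n_genera) {
    stop("n_species (", spec$n_species, ") smaller than the number of ",
         "genera (", n_genera, ")")
  }
  sp_per_genus <- .partition_total(spec$n_species, n_genera)
  rows <- list()
  si <- 0L
  for (g in seq_len(n_genera)) {
    lg <- lineage[[g]]
    for (s in seq_len(sp_per_genus[g])) {
      si <- si + 1L
      sp_anc <- .mutate(lg$anc, spec$rates$species)
      sp_name <- sprintf("Species%03d", si)
      n_spec <- .rint(spec$specimens_per_species)
      for (r in seq_len(n_spec)) {
        chars <- .mutate(sp_anc, spec$rates$specimen)
        chars <- .indel(chars, spec$indel_rate, spec$indel_length)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_%02d", sp_name, r),
          seq = paste(chars, collapse = ""),
          class = lg$class, order = lg$order, family = lg$family,
          genus = lg$genus, species = sp_name,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  truth <- records[, c("id", "class", "order", "family", "genus",
                       "species")]
  truth$outlier <- FALSE
  attr(truth, "spec") <- spec
  list(records = records, truth = truth)
}

#' Spike length/GC outlier specimens into one species
#'
#' Emulates divergent barcode records occasionally found within a
#' species: `n` specimens of the target species are lengthened by
#' `length_delta` bp and their GC content is raised by `gc_delta`, which
#' shifts their natural vectors away from the species cloud (such records
#' tend to attach basally to their species clade in the single-linkage
#' tree).
#'
#' @param dataset A list with `records` and `truth` as returned by
#'   [generate_dataset()].
#' @param species Target species name; default the species with the most
#'   specimens.
#' @param n Number of specimens to modify (the first `n` of the species).
#' @param length_delta Added length in bp (>= 0).
#' @param gc_delta Added GC fraction (may be 0).
#' @return The dataset with modified records and `truth$outlier` flags
#'   set; the flagged ids are attached as attribute `"outlier_ids"` of
#'   the returned list.
#' @export
spike_outliers <- function(dataset, species = NULL, n = 2L,
                           length_delta = 120L, gc_delta = 0.05) {
  records <- dataset$records
  truth <- dataset$truth
  if (n == 0L) return(dataset)
  if (is.null(species)) {
    cnt <- table(records$species)
    species <- names(cnt)[which.max(cnt)]
  }
  idx <- which(records$species == species)
  if (length(idx) < n) {
    stop("species '", species, "' has only ", length(idx), " specimens")
  }
  idx <- idx[seq_len(n)]
  for (i in idx) {
    chars <- strsplit(records$seq[i], "", fixed = TRUE)[[1L]]
    gc_old <- mean(chars %in% c("G", "C"))
    gc_target <- gc_old + gc_delta
    if (gc_target > 1 || gc_target < 0) {
      stop("gc_delta of ", gc_delta, " pushes GC fraction outside [0, 1]")
    }
    if (gc_delta > 0) {
      at <- which(chars %in% c("A", "T"))
      n_flip <- min(length(at),
                    ceiling((gc_target - gc_old) * length(chars)))
      flip <- sample(at, n_flip)
      chars[flip] <- sample(c("G", "C"), n_flip, replace = TRUE)
    }
    if (length_delta > 0) {
      # compose the added tail so the final GC fraction lands on target
      n_final <- length(chars) + length_delta
      gc_have <- sum(chars %in% c("G", "C"))
      gc_need <- max(0L, min(length_delta,
                             round(gc_target * n_final) - gc_have))
      tail <- c(sample(c("G", "C"), gc_need, replace = TRUE),
                sample(c("A", "T"), length_delta - gc_need,
                       replace = TRUE))
      chars <- c(chars, sample(tail))
    }
    records$seq[i] <- paste(chars, collapse = "")
  }
  truth$outlier[truth$id %in% records$id[idx]] <- TRUE
  out <- list(records = records, truth = truth)
  attr(out, "outlier_ids") <- records$id[idx]
  out
}

#' Write a synthetic dataset as FASTA plus taxonomy TSV
#'
#' @param dataset List with `records` and `truth`.
#' @param fasta,taxonomy Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_dataset <- function(dataset, fasta, taxonomy) {
  write_fasta(dataset$records, fasta)
  utils::write.table(dataset$truth[, c("id", "class", "order", "family",
                                       "genus", "species")],
                     taxonomy, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta, taxonomy = taxonomy))
}
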