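#' Read DNA barcode sequences from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file of barcode sequences. The header
#' token before the first whitespace becomes the record id; sequences are
#' uppercased but otherwise returned as found in the file, so IUPAC
#' ambiguity codes survive until [validate_sequence()] is applied.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with character columns `id` and `seq`, one row per
#'   FASTA entry, in file order.
#' @seealso [validate_records()], [read_taxonomy()]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "acg", "tac"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no sequences: ", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  data.frame(id = ids, seq = toupper(as.character(set)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write barcode records to a FASTA file
#'
#' @param records Data frame with columns `id` and `seq`.
#' @param path Output file path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Canonicalize a raw barcode sequence
#'
#' Uppercases, maps U to T, and resolves characters outside the canonical
#' alphabet \{A, C, G, T\} according to `policy`. Under `"strict"` any
#' remaining non-canonical character is an error; under `"drop-ambiguous"`
#' IUPAC ambiguity codes (N, R, Y, ...) and gap characters are removed and
#' positions renumber over the retained characters, which is the behaviour
#' real ITS barcodes need since the natural-vector definition only covers
#' the four canonical nucleotides.
#'
#' @param raw Non-empty character string.
#' @param policy `"strict"` or `"drop-ambiguous"`.
#' @return Canonical sequence string; the number of dropped characters is
#'   attached as attribute `"dropped"`.
#' @examples
#' validate_sequence("ACGUAC")          # RNA-style U mapped to T
#' validate_sequence("ACNGT")           # ambiguity code dropped
#' @export
validate_sequence <- function(raw, policy = c("drop-ambiguous", "strict")) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1L || nchar(raw) == 0L) {
    stop("sequence must be a single non-empty string")
  }
  s <- chartr("U", "T", toupper(raw))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (policy == "strict") {
    if (length(bad) > 0L) {
      stop("non-canonical character '", chars[bad[1L]],
           "' at position ", bad[1L])
    }
    dropped <- 0L
  } else {
    dropped <- length(bad)
    if (dropped > 0L) chars <- chars[-bad]
    if (length(chars) == 0L) {
      stop("sequence empty after dropping ambiguous characters")
    }
    s <- paste(chars, collapse = "")
  }
  structure(s, dropped = dropped)
}

#' Validate every sequence in a record table
#'
#' Applies [validate_sequence()] to each record and reports the total count
#' of dropped ambiguity characters.
#'
#' @param records Data frame with columns `id` and `seq`.
#' @inheritParams validate_sequence
#' @param quiet Suppress the message about dropped characters.
#' @return `records` with canonicalized sequences.
#' @export
validate_records <- function(records, policy = c("drop-ambiguous", "strict"),
                             quiet = FALSE) {
  policy <- match.arg(policy)
  dropped <- 0L
  for (i in seq_len(nrow(records))) {
    v <- tryCatch(validate_sequence(records$seq[i], policy),
                  error = function(e) {
                    stop("record '", records$id[i], "': ", conditionMessage(e),
                         call. = FALSE)
                  })
    dropped <- dropped + attr(v, "dropped")
    records$seq[i] <- as.character(v)
  }
  if (!quiet && dropped > 0L) {
    message("dropped ", dropped, " ambiguous/gap character(s) across ",
            nrow(records), " record(s)")
  }
  records
}

.rank_cols <- c("class", "order", "family", "genus", "species")

#' Read a taxonomy table and join it onto barcode records
#'
#' The taxonomy table is a TSV with header
#' `id class order family genus species`. Records absent from the table get
#' empty taxonomy labels.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `id`, `class`, `order`, `family`,
#'   `genus`, `species`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file does not exist: ", path)
  tx <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", .rank_cols)
  miss <- setdiff(need, names(tx))
  if (length(miss) > 0L) {
    stop("taxonomy table lacks column(s): ", paste(miss, collapse = ", "))
  }
  tx[, need]
}

#' @rdname read_taxonomy
#' @param records Data frame with column `id`.
#' @param taxonomy Data frame as returned by `read_taxonomy()`.
#' @export
attach_taxonomy <- function(records, taxonomy) {
  m <- match(records$id, taxonomy$id)
  for (rk in .rank_cols) {
    records[[rk]] <- ifelse(is.na(m), "", taxonomy[[rk]][m])
    records[[rk]][is.na(records[[rk]])] <- ""
  }
  records
}

#' Filter records on taxonomy completeness and species sample size
#'
#' Mirrors the curation applied to barcode repositories before
#' classification: records without a complete five-rank taxonomy
#' (class, order, family, genus, species all non-empty) are removed when
#' `require_full_taxonomy` is set, and then every species represented by
#' fewer than `min_specimens_per_species` specimens is removed entirely
#' (with the threshold at 2 this strips singleton species, which cannot be
#' identified by a within-species vote).
#'
#' @param records Data frame with `id`, `seq` and the five rank columns.
#' @param require_full_taxonomy Remove records with any empty rank label.
#' @param min_specimens_per_species Minimum specimens a species must retain.
#' @return A list with elements `records` (the retained rows) and `removed`
#'   (a data frame of `id`, `reason` for every removed record).
#' @export
filter_dataset <- function(records, require_full_taxonomy = TRUE,
                           min_specimens_per_species = 1L) {
  stopifnot(is.data.frame(records))
  for (rk in .rank_cols) {
    if (is.null(records[[rk]])) records[[rk]] <- ""
  }
  removed <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  keep <- records
  if (isTRUE(require_full_taxonomy)) {
    full <- Reduce(`&`, lapply(.rank_cols, function(rk) {
      !is.na(keep[[rk]]) & nzchar(keep[[rk]])
    }))
    if (any(!full)) {
      removed <- rbind(removed, data.frame(
        id = keep$id[!full], reason = "incomplete_taxonomy",
        stringsAsFactors = FALSE))
      keep <- keep[full, , drop = FALSE]
    }
  }
  if (min_specimens_per_species > 1L && nrow(keep) > 0L) {
    cnt <- table(keep$species)
    small <- names(cnt)[cnt < min_specimens_per_species]
    drop <- keep$species %in% small
    if (any(drop)) {
      removed <- rbind(removed, data.frame(
        id = keep$id[drop], reason = "species_below_min_specimens",
        stringsAsFactors = FALSE))
      keep <- keep[!drop, , drop = FALSE]
    }
  }
  if (nrow(keep) == 0L) warning("all records removed by filtering")
  rownames(keep) <- NULL
  list(records = keep, removed = removed)
}

#' Per-sequence length and GC content
#'
#' @param x A single sequence string or a record data frame with
#'   `id` and `seq` columns.
#' @return For a single string, a list with `length` and `gc_fraction`;
#'   for a data frame, one row per record with `id`, `length`,
#'   `gc_fraction`.
#' @examples
#' seq_stats("ACGTAC")   # length 6, GC 0.5
#' @export
seq_stats <- function(x) {
  one <- function(s) {
    n <- nchar(s)
    gc <- sum(strsplit(s, "", fixed = TRUE)[[1L]] %in% c("G", "C"))
    list(length = n, gc_fraction = gc / n)
  }
  if (is.character(x) && length(x) == 1L) {
    return(one(x))
  }
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  st <- lapply(x$seq, one)
  data.frame(id = x$id,
             length = vapply(st, `[[`, numeric(1), "length"),
             gc_fraction = vapply(st, `[[`, numeric(1), "gc_fraction"),
             stringsAsFactors = FALSE)
}
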