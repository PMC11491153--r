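#' Read transcript sequences from a FASTA file
#'
#' Reads a (plain or gzipped) FASTA file into a transcript table. Record IDs
#' are taken from the header up to the first whitespace; `U` is mapped to `T`
#' internally (the folding engine maps back to RNA). By default any character
#' outside `A`, `C`, `G`, `T`, `U` — including ambiguity codes such as `N` —
#' is an error; with `mask_ambiguous = TRUE` such characters are kept as `N`
#' and k-mers touching them are dropped at extraction time.
#'
#' @param path Path to a FASTA file.
#' @param mask_ambiguous Keep non-ACGTU IUPAC characters as `N` instead of
#'   erroring. Default `FALSE`.
#' @return A tibble with columns `id`, `sequence`, `length` (nt), one row per
#'   record in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">tx1 demo", "ACGTACGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path, mask_ambiguous = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  recs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(recs) == 0L) abort(paste0("no FASTA records in ", path))
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate transcript ID(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- normalize_nt(unname(as.character(recs)), ids, mask_ambiguous)
  tibble(id = ids, sequence = seqs, length = nchar(seqs))
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' @param path Path to a FASTA or FASTQ file (plain or gzipped). The format
#'   is taken from the extension (`.fq`/`.fastq` vs anything else).
#' @return A character vector of read sequences (uppercase, `U` mapped to `T`).
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
    "fastq"
  } else {
    "fasta"
  }
  recs <- Biostrings::readBStringSet(path, format = fmt)
  if (length(recs) == 0L) abort(paste0("no reads in ", path))
  chartr("Uu", "TT", toupper(as.character(unname(recs))))
}

# uppercase, U->T, validate or mask; names used only for error messages
normalize_nt <- function(seqs, ids, mask_ambiguous) {
  seqs <- chartr("Uu", "TT", toupper(seqs))
  bad <- gregexpr("[^ACGT]", seqs)
  for (i in seq_along(seqs)) {
    pos <- bad[[i]]
    if (pos[1] == -1L) next
    chars <- substring(seqs[i], pos, pos)
    if (!mask_ambiguous) {
      abort(paste0(
        "sequence '", ids[i], "' contains non-ACGTU character(s) ",
        paste0(unique(chars), collapse = ","), " at position(s) ",
        paste0(head(pos, 5L), collapse = ","),
        if (length(pos) > 5L) " ..." else "",
        "; use mask_ambiguous = TRUE to mask them as N"
      ))
    }
    if (any(!chars %in% c("N"))) {
      s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      s[pos] <- "N"
      seqs[i] <- paste0(s, collapse = "")
    }
  }
  seqs
}

#' Count G and C bases in a sequence
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Integer vector: number of `G` or `C` characters (case-insensitive)
#'   in each sequence.
#' @export
#' @examples
#' gc_count(c("ATCG", "GCGC"))
gc_count <- function(seq) {
  as.integer(stringr::str_count(seq, "[GCgc]"))
}

#' Extract all k-mers of a set of transcripts
#'
#' Slides a window of width `k` (step 1) over each transcript from its 5'
#' end, producing one record per start position: `max(L - k + 1, 0)` records
#' for a transcript of length `L`. Modeling counts are initialised to 1
#' (the uniform-coverage assumption), observed counts to 0. K-mer sequences
#' occurring at more than one position in the table are flagged `duplicated`;
#' such positions later share one observed count.
#'
#' @param transcripts Transcript tibble as returned by [read_fasta()]
#'   (columns `id`, `sequence`), or any data frame with those columns.
#' @param k Window width in nt. Default 50.
#' @return A k-mer tibble with columns `transcript_id`, `start0` (0-based),
#'   `start1` (1-based, for human reading), `kmer`, `gc`, `mfe` (`NA` until
#'   [add_mfe()]), `count_obs`, `count_model`, `count_cal`, `duplicated`.
#'   Transcripts shorter than `k` contribute no rows and raise a warning.
#' @export
#' @examples
#' tx <- tibble::tibble(id = "t1", sequence = "ACGTACGTACGT")
#' extract_kmers(tx, k = 8)
extract_kmers <- function(transcripts, k = 50) {
  stopifnot(is.data.frame(transcripts),
            all(c("id", "sequence") %in% names(transcripts)))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) abort("k must be a positive integer")
  L <- nchar(transcripts$sequence)
  n <- pmax(L - k + 1L, 0L)
  if (any(n == 0L)) {
    short <- transcripts$id[n == 0L]
    warn(paste0(length(short), " transcript(s) shorter than k = ", k,
                " contribute no k-mers (e.g. '", short[1], "')"))
  }
  idx <- rep.int(seq_along(n), n)
  start0 <- sequence(n) - 1L
  km <- substring(transcripts$sequence[idx], start0 + 1L, start0 + k)
  out <- tibble(
    transcript_id = transcripts$id[idx], start0 = start0,
    start1 = start0 + 1L, kmer = km, gc = gc_count(km), mfe = NA_real_,
    count_obs = 0, count_model = 1, count_cal = NA_real_
  )
  if (nrow(out) == 0L) {
    out$duplicated <- logical(0)
    return(out)
  }
  masked <- grepl("N", out$kmer, fixed = TRUE)
  if (any(masked)) {
    warn(paste0(sum(masked), " k-mer(s) containing masked bases dropped"))
    out <- out[!masked, , drop = FALSE]
  }
  out$duplicated <- out$kmer %in% out$kmer[duplicated(out$kmer)]
  out
}

#' Count occurrences of query k-mers in sequencing reads
#'
#' Every length-`k` substring of every read (step 1) is matched exactly
#' against the query set; counts accumulate per distinct k-mer sequence.
#' With `strand = "both"` the reverse complement of each read substring is
#' matched as well. Reads shorter than `k` are skipped and tallied, never
#' padded. Counting is additive over read batches.
#'
#' @param reads Character vector of read sequences (see [read_reads()]).
#' @param kmers Character vector of query k-mers, all of one length `k`.
#' @param strand `"forward"` (default; stranded library) or `"both"`.
#' @return A tibble with columns `kmer`, `count` (one row per distinct query,
#'   in first-appearance order), with attributes `n_reads`, `n_skipped`
#'   (reads shorter than `k`) and `total_matches`.
#' @export
count_kmers_in_reads <- function(reads, kmers, strand = c("forward", "both")) {
  strand <- match.arg(strand)
  kmers <- unique(as.character(kmers))
  if (length(kmers) == 0L) abort("empty k-mer query set")
  k <- unique(nchar(kmers))
  if (length(k) != 1L) abort("query k-mers must all have the same length")
  reads <- chartr("Uu", "TT", toupper(as.character(reads)))
  keep <- nchar(reads) >= k
  n_skipped <- sum(!keep)
  subs <- unlist(purrr::map(reads[keep], function(r) {
    s0 <- 1:(nchar(r) - k + 1L)
    substring(r, s0, s0 + k - 1L)
  }), use.names = FALSE)
  counts <- tabulate(factor(subs, levels = kmers), nbins = length(kmers))
  if (strand == "both" && length(subs) > 0L) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(subs)))
    counts <- counts + tabulate(factor(rc, levels = kmers), nbins = length(kmers))
  }
  out <- tibble(kmer = kmers, count = as.numeric(counts))
  attr(out, "n_reads") <- length(reads)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "total_matches") <- sum(counts)
  out
}

#' Attach observed counts to a k-mer table
#'
#' Joins per-sequence counts (from [count_kmers_in_reads()] or an external
#' TSV) onto a k-mer table. A k-mer sequence occurring at several positions
#' shares one observed count, assigned to every position carrying it
#' (positions are bookkeeping; counts are per sequence). Sequences absent
#' from `counts` get 0.
#'
#' @param kmers K-mer tibble from [extract_kmers()].
#' @param counts Data frame with columns `kmer` and `count` (or a named
#'   numeric vector).
#' @return `kmers` with `count_obs` filled.
#' @export
add_observed_counts <- function(kmers, counts) {
  if (!is.data.frame(counts)) {
    counts <- tibble(kmer = names(counts), count = as.numeric(counts))
  }
  stopifnot(all(c("kmer", "count") %in% names(counts)))
  idx <- match(kmers$kmer, counts$kmer)
  kmers$count_obs <- ifelse(is.na(idx), 0, counts$count[idx])
  kmers
}

#' Write / read a k-mer table as TSV
#'
#' The on-disk schema is `transcript_id, start0, start1, kmer, gc, mfe,
#' count_obs, count_model, count_cal, category_id, duplicated`.
#'
#' @param kmers K-mer tibble.
#' @param path Output (input) TSV path.
#' @return `write_kmer_table()` returns `path` invisibly; `read_kmer_table()`
#'   returns the k-mer tibble.
#' @export
write_kmer_table <- function(kmers, path) {
  if (!"category_id" %in% names(kmers)) kmers$category_id <- NA_character_
  cols <- c("transcript_id", "start0", "start1", "kmer", "gc", "mfe",
            "count_obs", "count_model", "count_cal", "category_id",
            "duplicated")
  readr::write_tsv(kmers[, intersect(cols, names(kmers))], path)
  invisible(path)
}

#' @rdname write_kmer_table
#' @export
read_kmer_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
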