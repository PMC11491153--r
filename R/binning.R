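#' Categorize k-mers by GC content or MFE and aggregate counts
#'
#' Groups k-mers into categories keyed by their integer GC count or by their
#' rounded MFE value (one category per distinct rounded value — not interval
#' bins), and aggregates the modeling and observed counts per category.
#' Every k-mer maps to exactly one category; category values are strictly
#' increasing.
#'
#' @param kmers K-mer tibble (columns `gc`, `count_model`, `count_obs`; for
#'   `key = "mfe"` also a fully populated `mfe` column).
#' @param key `"mfe"` (default) or `"gc"`.
#' @param precision MFE rounding quantum (kcal/mol) defining category
#'   identity. Default 0.1, matching the folding engine.
#' @return A tibble of class `kcat_tbl` with columns `category` (ascending
#'   key value), `n_kmers`, `agg_model`, `agg_obs`, and attribute `key`.
#' @export
#' @examples
#' tx <- tibble::tibble(id = "t", sequence = strrep("ACGT", 30))
#' km <- extract_kmers(tx, k = 20)
#' categorize(km, key = "gc")
categorize <- function(kmers, key = c("mfe", "gc"), precision = 0.1) {
  key <- match.arg(key)
  if (!is.data.frame(kmers) || nrow(kmers) == 0L) {
    abort("categorize() needs a non-empty k-mer table")
  }
  val <- if (key == "gc") {
    as.numeric(kmers$gc)
  } else {
    if (anyNA(kmers$mfe)) abort("mfe column must be fully populated; run add_mfe() first")
    round(kmers$mfe / precision) * precision
  }
  out <- tibble(category = val,
                count_model = kmers$count_model,
                count_obs = kmers$count_obs) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_kmers = dplyr::n(),
                     agg_model = sum(.data$count_model),
                     agg_obs = sum(.data$count_obs),
                     .groups = "drop") |>
    dplyr::arrange(.data$category)
  attr(out, "key") <- key
  attr(out, "precision") <- precision
  class(out) <- c("kcat_tbl", class(out))
  out
}

#' @export
print.kcat_tbl <- function(x, ...) {
  cat("k-mer category table (key = ", attr(x, "key"), ", ",
      nrow(x), " categories, ", sum(x$n_kmers), " k-mers)\n", sep = "")
  NextMethod()
}

#' Linear relationship between GC content and MFE
#'
#' Ordinary least squares of mean MFE per GC class against the GC class
#' value, quantifying the inverse linear GC–MFE relationship that justifies
#' transferring the GC-based Gaussian model to MFE categories.
#'
#' @param kmers K-mer tibble with `gc` and `mfe` populated.
#' @return One-row tibble: `slope`, `intercept`, `r` (Pearson correlation of
#'   class means; `NA` with a warning when MFE is constant), `n_classes`.
#' @export
gc_mfe_regression <- function(kmers) {
  if (anyNA(kmers$mfe)) abort("mfe column must be fully populated")
  cls <- dplyr::summarise(dplyr::group_by(kmers, gc = .data$gc),
                          mean_mfe = mean(.data$mfe), .groups = "drop")
  if (nrow(cls) < 3L) abort("need at least 3 distinct GC classes")
  fit <- lm(mean_mfe ~ gc, data = cls)
  r <- if (sd(cls$mean_mfe) == 0) {
    warn("MFE constant across GC classes; correlation undefined")
    NA_real_
  } else {
    cor(cls$gc, cls$mean_mfe)
  }
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r = r, n_classes = nrow(cls))
}

#' Isoform overlap degree per k-mer start position
#'
#' For every k-mer of every isoform, the overlap degree is the number of
#' isoforms in the supplied set (including the isoform itself) whose
#' sequence contains that exact k-mer as a substring. Runs of degree 1
#' define regions unique to one isoform.
#'
#' @param isoforms Transcript tibble (columns `id`, `sequence`), one row per
#'   isoform.
#' @param k K-mer width. Default 50.
#' @return A tibble with columns `transcript_id`, `start0`, `kmer`, `degree`
#'   (integer ≥ 1).
#' @export
overlap_degree <- function(isoforms, k = 50) {
  stopifnot(is.data.frame(isoforms), nrow(isoforms) >= 1L)
  km <- extract_kmers(isoforms, k = k)
  # number of isoforms carrying each k-mer sequence
  carriers <- dplyr::distinct(km, .data$transcript_id, .data$kmer) |>
    dplyr::count(.data$kmer, name = "degree")
  out <- dplyr::left_join(
    km[, c("transcript_id", "start0", "kmer")], carriers, by = "kmer"
  )
  out$degree <- as.integer(out$degree)
  out
}

#' Unique (degree-1) regions of an overlap profile
#'
#' Maximal, disjoint, sorted runs of k-mer start positions with overlap
#' degree 1, per isoform. Intervals are 0-based half-open in k-mer start
#' space: `[start0, end0)` covers start positions `start0 .. end0 - 1`.
#'
#' @param profile Output of [overlap_degree()].
#' @return Tibble `transcript_id`, `start0`, `end0`, `n_kmers`.
#' @export
unique_regions <- function(profile) {
  degree_runs(profile, max_degree = 1L)
}

# maximal runs of consecutive start positions with degree <= max_degree
degree_runs <- function(profile, max_degree) {
  profile |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(.data$start0, .by_group = TRUE) |>
    dplyr::group_modify(function(d, g) {
      ok <- d$degree <= max_degree
      if (!any(ok)) {
        return(tibble(start0 = integer(0), end0 = integer(0),
                      n_kmers = integer(0), max_degree = integer(0)))
      }
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      tibble(
        start0 = d$start0[starts[keep]],
        end0 = d$start0[ends[keep]] + 1L,
        n_kmers = r$lengths[keep],
        max_degree = vapply(keep, function(i) {
          max(d$degree[starts[i]:ends[i]])
        }, integer(1))
      )
    }) |>
    dplyr::ungroup()
}

#' Select the quantification region of an isoform
#'
#' Prefers the longest run of overlap degree 1 (a region unique to the
#' isoform, any length); failing that, searches contiguous minimal-shared
#' regions of increasing maximum degree up to `max_degree`, requiring at
#' least `min_kmers` k-mer starts; failing that, the isoform is
#' unquantifiable.
#'
#' @param profile Output of [overlap_degree()], filtered or not.
#' @param transcript_id Isoform to select a region for.
#' @param max_degree Largest acceptable overlap degree. Default 1.
#' @param min_kmers Minimum run length (k-mer starts) for shared regions of
#'   degree > 1. Default 100.
#' @return One-row tibble `transcript_id`, `status` (`"unique"`,
#'   `"minimal_shared"` or `"unquantifiable"`), `start0`, `end0`, `n_kmers`,
#'   `degree_used`.
#' @export
select_region <- function(profile, transcript_id, max_degree = 1,
                          min_kmers = 100) {
  p <- profile[profile$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(p) == 0L) abort(paste0("no profile rows for ", transcript_id))
  for (d in seq_len(max_degree)) {
    runs <- degree_runs(p, max_degree = d)
    if (d > 1L) runs <- runs[runs$n_kmers >= min_kmers, , drop = FALSE]
    if (nrow(runs) > 0L) {
      best <- runs[which.max(runs$n_kmers), , drop = FALSE]
      return(tibble(
        transcript_id = transcript_id,
        status = if (d == 1L) "unique" else "minimal_shared",
        start0 = best$start0, end0 = best$end0, n_kmers = best$n_kmers,
        degree_used = d
      ))
    }
  }
  tibble(transcript_id = transcript_id, status = "unquantifiable",
         start0 = NA_integer_, end0 = NA_integer_, n_kmers = 0L,
         degree_used = NA_integer_)
}

#' Write an overlap profile as BED-like TSV
#'
#' Transcript-space coordinates, 0-based half-open, one row per unique
#' region (`unique_regions()` output) or per position (`overlap_degree()`
#' output).
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @export
write_overlap_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
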