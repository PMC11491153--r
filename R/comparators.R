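#' LOESS GC-content weighting factors for fragments
#'
#' The GC-bias comparator: fragment GC percentages are binned at
#' `bin_width` (0.5 percentage points by default), per-bin fragment counts
#' are smoothed by LOESS (tricube-weighted local linear regression at the
#' given span), and the weight of a bin is the global mean bin count
#' divided by its smoothed count (floored at `pseudocount` so weights stay
#' finite).
#'
#' @param fragments Fragment tibble (`transcript_id`, `start0`, `end0`; see
#'   [simulate_fragments()]).
#' @param transcripts Transcript tibble supplying the sequences.
#' @param span LOESS span. Default 0.3.
#' @param bin_width GC%% bin width. Default 0.5.
#' @param pseudocount Floor for smoothed counts. Default 0.5.
#' @return A `weight_tbl` tibble: `key` (bin lower edge, GC%%), `n`
#'   (fragments in bin), `weight` (> 0, finite); attributes `kind = "gc_bin"`
#'   and `pseudocount`.
#' @export
loess_gc_weights <- function(fragments, transcripts, span = 0.3,
                             bin_width = 0.5, pseudocount = 0.5) {
  fr <- add_fragment_seq_stats(fragments, transcripts)
  fr$bin <- floor(fr$gc_pct / bin_width) * bin_width
  bins <- dplyr::count(fr, key = .data$bin)
  if (nrow(bins) < 10L) {
    abort(paste0("only ", nrow(bins), " occupied GC bins (need >= 10); ",
                 "consider a coarser bin_width"))
  }
  lo <- loess(n ~ key, data = bins, span = span, degree = 1,
              family = "gaussian",
              control = stats::loess.control(surface = "direct"))
  smoothed <- pmax(predict(lo, bins$key), pseudocount)
  bins$weight <- mean(bins$n) / smoothed
  new_weight_tbl(bins[, c("key", "n", "weight")], kind = "gc_bin",
                 pseudocount = pseudocount)
}

new_weight_tbl <- function(x, kind, pseudocount) {
  stopifnot(all(is.finite(x$weight)), all(x$weight > 0))
  attr(x, "kind") <- kind
  attr(x, "pseudocount") <- pseudocount
  class(x) <- c("weight_tbl", class(x))
  x
}

# derive per-fragment sequence, GC% and first hexamer from the transcripts
add_fragment_seq_stats <- function(fragments, transcripts) {
  idx <- match(fragments$transcript_id, transcripts$id)
  if (anyNA(idx)) abort("fragments reference transcripts absent from the table")
  seqs <- transcripts$sequence[idx]
  len <- fragments$end0 - fragments$start0
  if (any(len < 6)) abort("fragments shorter than 6 nt")
  fragments$length <- len
  fragments$seq <- substr(seqs, fragments$start0 + 1L, fragments$end0)
  fragments$gc_pct <- 100 * gc_count(fragments$seq) / len
  fragments$first6 <- substr(fragments$seq, 1L, 6L)
  fragments
}

#' Apply a weight table to counted records
#'
#' Multiplies a count column by the weight looked up per record key.
#' Records whose key is missing from the table get weight 1 with a warning.
#' Totals before and after are attached as attributes.
#'
#' @param df Data frame with the key column and a count column.
#' @param weights A `weight_tbl`.
#' @param key Name of the key column in `df`.
#' @param count Name of the count column. Default `"count"`.
#' @return `df` with an added `count_corrected` column.
#' @export
apply_weights <- function(df, weights, key, count = "count") {
  idx <- match(df[[key]], weights$key)
  w <- weights$weight[idx]
  if (anyNA(w)) {
    warn(paste0(sum(is.na(w)), " record(s) with keys absent from the weight",
                " table; weight 1 applied"))
    w[is.na(w)] <- 1
  }
  df$count_corrected <- df[[count]] * w
  attr(df, "total_raw") <- sum(df[[count]])
  attr(df, "total_corrected") <- sum(df$count_corrected)
  df
}

#' Global fragment-size Gaussian model
#'
#' Fits a free Gaussian to the histogram of fragment lengths pooled over
#' all transcripts, yielding the library-wide size parameters
#' \eqn{(\mu_f, \sigma_f)}.
#'
#' @param fragments Fragment tibble with `start0`, `end0` (or a `length`
#'   column).
#' @return A `gauss_fit` over integer length categories.
#' @export
fragment_size_model <- function(fragments) {
  len <- fragments$length %||% (fragments$end0 - fragments$start0)
  if (length(len) < 100L) abort("need at least 100 fragments for the global size fit")
  if (length(unique(len)) == 1L) abort("degenerate size distribution: all lengths equal")
  h <- dplyr::count(tibble(category = as.numeric(len)), .data$category,
                    name = "agg_model")
  h <- dplyr::arrange(h, .data$category)
  h$n_kmers <- 1L
  h$agg_obs <- h$agg_model
  fit_gaussian_free(h, which = "model")
}

#' Size-calibrated fragment count of each transcript
#'
#' Amplitude-only fit of each transcript's own length histogram at the
#' library-wide \eqn{(\mu_f, \sigma_f)} (PDF form, or the cumulative CDF
#' form); the amplitude is the size-calibrated fragment count.
#'
#' @param fragments Fragment tibble (`transcript_id`, `start0`, `end0`).
#' @param params A `gauss_fit` from [fragment_size_model()] (or a list with
#'   `mu` and `sigma`).
#' @param cdf Use the cumulative (CDF) amplitude fit. Default `FALSE`.
#' @return Tibble `transcript_id`, `n_fragments` (raw), `amplitude`
#'   (size-calibrated count).
#' @export
calibrate_by_size <- function(fragments, params, cdf = FALSE) {
  len <- fragments$length %||% (fragments$end0 - fragments$start0)
  # histograms are laid on the full integer length grid of the global fit
  # (zeros filled) so truncated size ranges inform the amplitude
  grid <- seq(min(params$data$x, len), max(params$data$x, len))
  g_grid <- exp(-(grid - params$mu)^2 / (2 * params$sigma^2))
  dplyr::group_by(tibble(transcript_id = fragments$transcript_id,
                         length = as.numeric(len)),
                  .data$transcript_id) |>
    dplyr::group_modify(function(d, gkey) {
      h <- tibble(
        category = as.numeric(grid),
        n_kmers = 1L,
        agg_obs = tabulate(factor(d$length, levels = grid),
                           nbins = length(grid))
      )
      h$agg_model <- h$agg_obs
      fit <- if (cdf) {
        fit_cdf_amplitude(h, mu = params$mu, sigma = params$sigma)
      } else {
        fit_amplitude_fixed(h, mu = params$mu, sigma = params$sigma)
      }
      # the PDF amplitude is a peak height; times the unit-Gaussian mass on
      # the grid it becomes the implied total fragment count
      scale <- if (cdf) 1 else sum(g_grid)
      tibble(n_fragments = nrow(d), amplitude = fit$amplitude * scale)
    }) |>
    dplyr::ungroup()
}

#' Hexamer priming weighting factors
#'
#' Counts how often each of the 4096 hexamers opens a fragment, sets the
#' theoretical even distribution (total/4096) as baseline, and computes
#' `weight_h = baseline / (n_h + pseudocount)`, rescaled so the
#' count-weighted mean weight is 1 (corrected library size equals raw
#' library size). The table always has all 4096 rows.
#'
#' @param fragments Fragment tibble; `first6` is derived from `transcripts`
#'   when absent.
#' @param transcripts Transcript tibble (needed unless `fragments$first6`
#'   exists).
#' @param pseudocount Added to every hexamer count so zero-count hexamers
#'   keep finite weights. Default 0.5.
#' @return A `weight_tbl`: `key` (hexamer), `n`, `weight`; 4096 rows.
#' @export
hexamer_weights <- function(fragments, transcripts = NULL, pseudocount = 0.5) {
  if (!"first6" %in% names(fragments)) {
    if (is.null(transcripts)) abort("supply transcripts to derive fragment hexamers")
    fragments <- add_fragment_seq_stats(fragments, transcripts)
  }
  hexamers <- all_hexamers()
  n_total <- nrow(fragments)
  if (n_total < 4096L) {
    warn(paste0("only ", n_total, " fragments for 4096 hexamers; ",
                "weights will be dominated by the pseudocount"))
  }
  n_h <- tabulate(factor(fragments$first6, levels = hexamers), nbins = 4096L)
  baseline <- n_total / 4096
  w <- baseline / (n_h + pseudocount)
  scale_tot <- sum(n_h * w)
  if (scale_tot > 0) w <- w * n_total / scale_tot
  new_weight_tbl(tibble(key = hexamers, n = n_h, weight = w),
                 kind = "hexamer", pseudocount = pseudocount)
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p6 = b, p5 = b, p4 = b, p3 = b, p2 = b, p1 = b,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3, g$p4, g$p5, g$p6)
}

#' Smoothing-based predicted counts per category
#'
#' The empirical baseline to the GSB fits: LOESS (tricube local linear) of
#' the observed aggregates over the category value; predictions are clamped
#' at 0. With few categories the span is widened to keep at least four
#' points in each local window. Per-k-mer averaging via [calibrate_kmers()]
#' works on the result.
#'
#' @param table A `kcat_tbl` (at least 5 categories).
#' @param span LOESS span. Default 0.3.
#' @return An object of class `smooth_fit` with `data` (tibble `x`,
#'   `n_kmers`, `y`, `predicted`, `residual`), `key`, `precision`, `span`.
#' @export
smooth_category_counts <- function(table, span = 0.3) {
  x <- table$category
  y <- table$agg_obs
  if (length(x) < 5L) abort("need at least 5 categories to smooth")
  span_eff <- max(span, min(1, 4 / length(x)))
  lo <- loess(y ~ x, span = span_eff, degree = 1, family = "gaussian",
              control = stats::loess.control(surface = "direct"))
  predicted <- pmax(predict(lo, x), 0)
  structure(list(
    key = attr(table, "key"), precision = attr(table, "precision"),
    span = span_eff,
    data = tibble(x = x, n_kmers = table$n_kmers, y = y,
                  predicted = predicted, residual = y - predicted)
  ), class = "smooth_fit")
}
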