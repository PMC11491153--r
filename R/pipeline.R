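#' Run the full GSB calibration pipeline on one transcript set
#'
#' Extract k-mers, fold (for MFE keying), attach observed counts,
#' categorize, fit the free Gaussian to the modeling aggregates, fit the
#' amplitude to the observed aggregates with the modeling mean/SD fixed,
#' and redistribute predictions to single k-mers.
#'
#' @param transcripts Transcript tibble ([read_fasta()] output or a path to
#'   a FASTA file), or an already-built k-mer tibble (a `kmer` column is
#'   taken as the signal; extraction is then skipped).
#' @param counts Observed counts: data frame `kmer`, `count` or a named
#'   numeric vector (see [add_observed_counts()]). Ignored when `reads` is
#'   given or the k-mer table already carries `count_obs`.
#' @param reads Read sequences (character vector or FASTA/FASTQ path) to
#'   count the k-mers in.
#' @param k K-mer width. Default 50.
#' @param key `"mfe"` (default) or `"gc"`.
#' @param engine A [fold_engine()] or engine name; an unavailable `"vienna"`
#'   engine falls back to `"builtin"` with a warning.
#' @param strand Strand handling for read counting.
#' @param weighted,r2_floor Passed to the fits.
#' @return An object of class `gsb_run`: `kmers` (calibrated table),
#'   `categories`, `model_fit` (`gauss_fit`), `amp_fit`, `cv_before`,
#'   `cv_after`, `config`.
#' @export
gsb_calibrate <- function(transcripts, counts = NULL, reads = NULL, k = 50,
                          key = c("mfe", "gc"), engine = fold_engine(),
                          strand = "forward", weighted = FALSE,
                          r2_floor = 0.9) {
  key <- match.arg(key)
  engine <- resolve_engine(engine)
  if (is.character(transcripts)) transcripts <- read_fasta(transcripts)
  km <- if ("kmer" %in% names(transcripts)) {
    transcripts
  } else {
    extract_kmers(transcripts, k = k)
  }
  if (key == "mfe" && anyNA(km$mfe)) km <- add_mfe(km, engine)
  if (!is.null(reads)) {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
      reads <- read_reads(reads)
    }
    counts <- count_kmers_in_reads(reads, unique(km$kmer), strand = strand)
  }
  if (!is.null(counts)) km <- add_observed_counts(km, counts)
  tab <- categorize(km, key = key,
                    precision = engine$precision)
  model_fit <- fit_gaussian_free(tab, which = "model", weighted = weighted,
                                 r2_floor = r2_floor)
  if (model_fit$degenerate) {
    abort("degenerate modeling fit: cannot calibrate", class = "gsb_degenerate")
  }
  amp <- fit_amplitude_fixed(tab, model_fit, weighted = weighted)
  km <- calibrate_kmers(km, amp)
  structure(list(
    kmers = km, categories = tab, model_fit = model_fit, amp_fit = amp,
    cv_before = cv(km$count_obs), cv_after = cv(km$count_cal),
    config = list(k = k, key = key, engine = engine$name,
                  temperature = engine$temperature,
                  precision = engine$precision, strand = strand,
                  weighted = weighted, r2_floor = r2_floor)
  ), class = "gsb_run")
}

resolve_engine <- function(engine) {
  if (inherits(engine, "fold_engine")) return(engine)
  tryCatch(fold_engine(engine), error = function(e) {
    warn(paste0("engine '", engine, "' unavailable (", conditionMessage(e),
                "); falling back to builtin"))
    fold_engine("builtin")
  })
}

#' Per-isoform abundance via unique-region CDF amplitudes
#'
#' For each isoform: compute the overlap-degree profile against the whole
#' set, select a quantification region (unique degree-1 run, else a
#' minimal-shared run up to `max_degree` of at least `min_kmers` starts),
#' categorize its k-mers by MFE, predetermine the Gaussian parameters from
#' the region's modeling data, and fit the fixed-parameter Gaussian CDF to
#' the cumulative observed aggregates. The amplitude is the bias-corrected
#' cumulative count of the region. Isoforms with no admissible region are
#' reported `unquantifiable`, never silently zero.
#'
#' @param isoforms Transcript tibble or FASTA path (>= 1 isoform).
#' @param counts,reads Observed signal, as in [gsb_calibrate()].
#' @param k K-mer width. Default 50.
#' @param engine A [fold_engine()] or name.
#' @param strand Strand handling for read counting.
#' @param max_degree,min_kmers Region selection; see [select_region()].
#' @param refit_cdf Derive (mu, sigma) from a free CDF fit of the modeling
#'   data instead of reusing the PDF-fit parameters. Default `FALSE`.
#' @param library_total Optional total mapped count for RPKM.
#' @return Tibble: `transcript_id`, `status`, `start0`, `end0`, `n_kmers`,
#'   `degree_used`, `amplitude`, `per_kmer` (amplitude / n_kmers),
#'   `region_length_nt`, plus `rpkm` (if `library_total`) and `tpm` over
#'   the quantifiable isoforms.
#' @export
gsb_abundance <- function(isoforms, counts = NULL, reads = NULL, k = 50,
                          engine = fold_engine(), strand = "forward",
                          max_degree = 1, min_kmers = 100,
                          refit_cdf = FALSE, library_total = NULL) {
  engine <- resolve_engine(engine)
  if (is.character(isoforms)) isoforms <- read_fasta(isoforms)
  stopifnot(nrow(isoforms) >= 1L)
  profile <- overlap_degree(isoforms, k = k)
  if (!is.null(reads)) {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
      reads <- read_reads(reads)
    }
    counts <- count_kmers_in_reads(reads, unique(profile$kmer),
                                   strand = strand)
  }
  rows <- purrr::map(isoforms$id, function(id) {
    reg <- select_region(profile, id, max_degree = max_degree,
                         min_kmers = min_kmers)
    if (reg$status == "unquantifiable") {
      return(dplyr::mutate(reg, amplitude = NA_real_, per_kmer = NA_real_,
                           region_length_nt = NA_integer_))
    }
    km <- extract_kmers(isoforms[isoforms$id == id, , drop = FALSE], k = k)
    km <- km[km$start0 >= reg$start0 & km$start0 < reg$end0, , drop = FALSE]
    km <- add_mfe(km, engine)
    if (!is.null(counts)) km <- add_observed_counts(km, counts)
    tab <- categorize(km, key = "mfe", precision = engine$precision)
    params <- if (refit_cdf) {
      fit_gaussian_cdf_free(tab, which = "model")
    } else {
      fit_gaussian_free(tab, which = "model")
    }
    amp <- fit_cdf_amplitude(tab, params)
    dplyr::mutate(reg, amplitude = amp$amplitude,
                  per_kmer = amp$amplitude / reg$n_kmers,
                  region_length_nt = reg$n_kmers + as.integer(k) - 1L)
  })
  out <- dplyr::bind_rows(rows)
  q <- !is.na(out$amplitude)
  out$tpm <- NA_real_
  if (any(q)) {
    rate <- out$amplitude[q] / out$region_length_nt[q]
    out$tpm[q] <- rate / sum(rate) * 1e6
  }
  if (!is.null(library_total)) {
    out$rpkm <- out$amplitude / (out$region_length_nt / 1e3) /
      (library_total / 1e6)
  }
  out
}

#' Compare GSB against smoothing on one dataset
#'
#' Runs GC-GSB, MFE-GSB, GC-smoothing and MFE-smoothing calibration on the
#' same k-mer table and reports per-k-mer corrected counts plus a CV
#' summary (the package's uniformity metric).
#'
#' @param kmers K-mer tibble with `gc`, `mfe` and `count_obs` populated.
#' @param span Smoothing span. Default 0.3.
#' @param weighted Weight GSB fits by `n_kmers`.
#' @param precision MFE category precision. Default 0.1.
#' @return An object of class `gsb_comparison`: `kmers` (one row per input
#'   k-mer, columns `count_obs`, `cal_gc_gsb`, `cal_mfe_gsb`,
#'   `cal_gc_smooth`, `cal_mfe_smooth`), `categories` (named list of
#'   per-key tables with GSB and smoothing predictions) and `summary`
#'   (tibble `method`, `cv`).
#' @export
gsb_compare <- function(kmers, span = 0.3, weighted = FALSE,
                        precision = 0.1) {
  stopifnot(all(c("gc", "mfe", "count_obs") %in% names(kmers)))
  if (anyNA(kmers$mfe)) abort("mfe column must be populated; run add_mfe()")
  out <- kmers
  cats <- list()
  for (key in c("gc", "mfe")) {
    tab <- categorize(kmers, key = key, precision = precision)
    model_fit <- fit_gaussian_free(tab, which = "model", weighted = weighted)
    amp <- fit_amplitude_fixed(tab, model_fit, weighted = weighted)
    smo <- smooth_category_counts(tab, span = span)
    out[[paste0("cal_", key, "_gsb")]] <-
      calibrate_kmers(kmers, amp)$count_cal
    out[[paste0("cal_", key, "_smooth")]] <-
      calibrate_kmers(kmers, smo)$count_cal
    tab$predicted_gsb <- amp$data$predicted
    tab$predicted_smooth <- smo$data$predicted
    cats[[key]] <- tab
  }
  methods <- c(raw = "count_obs", gc_gsb = "cal_gc_gsb",
               mfe_gsb = "cal_mfe_gsb", gc_smooth = "cal_gc_smooth",
               mfe_smooth = "cal_mfe_smooth")
  summary <- tibble(
    method = names(methods),
    cv = vapply(methods, function(cl) cv(out[[cl]]), numeric(1))
  )
  structure(list(kmers = out, categories = cats, summary = summary),
            class = "gsb_comparison")
}

#' Write a reproducibility manifest for a pipeline result
#'
#' Serializes the run configuration (inputs summary, parameters, seed,
#' package version) to JSON so deterministic stages can be re-run
#' bit-identically.
#'
#' @param x A `gsb_run`, `gsb_comparison`, or any list with a `config`
#'   element.
#' @param path Output JSON path.
#' @param extra Named list merged into the manifest (e.g. seeds, input
#'   paths).
#' @export
write_manifest <- function(x, path, extra = list()) {
  manifest <- c(
    list(package = "mfegsb",
         version = as.character(utils::packageVersion("mfegsb")),
         created = format(Sys.time(), tz = "UTC", usetz = TRUE),
         config = x$config %||% NULL),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
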