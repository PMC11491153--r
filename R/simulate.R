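#' Degenerate spike-in design
#'
#' The spike-in construct: a 50-nt core carrying `n` degenerate (`N`)
#' positions, flanked by poly-A tails. Enumerating the `N` positions yields
#' `4^n` variant sequences (65,536 for the default 8). The default backbone
#' is a synthetic, deterministic 42-nt scaffold with 8 interleaved `N`s —
#' a documented package constant, not a published spike-in sequence.
#'
#' @param backbone 50-character template containing the `N` positions.
#' @param flank5,flank3 Flanking sequences. Default 8-mer poly-A.
#' @return An object of class `spikein_design`.
#' @export
#' @examples
#' d <- spikein_design()
#' d$n_variable
spikein_design <- function(backbone = spikein_backbone(),
                           flank5 = strrep("A", 8),
                           flank3 = strrep("A", 8)) {
  backbone <- toupper(backbone)
  if (nchar(backbone) != 50L) abort("backbone must be exactly 50 nt")
  if (grepl("[^ACGTN]", backbone)) abort("backbone may contain only A,C,G,T,N")
  n <- stringr::str_count(backbone, "N")
  if (n > 12L) abort("more than 12 degenerate positions: enumeration too large")
  structure(list(backbone = backbone, flank5 = flank5, flank3 = flank3,
                 n_variable = n), class = "spikein_design")
}

#' @rdname spikein_design
#' @export
spikein_backbone <- function() {
  "GCTAGNCTGACNGTCAGNTTGACNGGATCNACGTGNCCATGNTGCAGNAC"
}

#' Enumerate all variants of a spike-in design
#'
#' Generates the `4^n` variant sequences by substituting every combination
#' of `A`, `C`, `G`, `T` at the degenerate positions, in lexicographic
#' `A < C < G < T` order of the variable-position string (first variable
#' position most significant). Deterministic.
#'
#' @param design A [spikein_design()].
#' @return Tibble with columns `id`, `variant` (the `n` variable bases),
#'   `core` (filled 50-mer) and `sequence` (flanked full construct).
#' @export
#' @examples
#' nrow(enumerate_spikeins(spikein_design()))  # 65536
enumerate_spikeins <- function(design) {
  stopifnot(inherits(design, "spikein_design"))
  n <- design$n_variable
  bases <- c("A", "C", "G", "T")
  total <- 4L^n
  if (n == 0L) {
    core <- design$backbone
    return(tibble(id = "spikein_0", variant = "",
                  core = core,
                  sequence = paste0(design$flank5, core, design$flank3)))
  }
  idx <- 0:(total - 1L)
  digits <- vapply(seq_len(n), function(j) {
    as.integer((idx %/% 4^(n - j)) %% 4)
  }, integer(total))
  if (n == 1L) digits <- matrix(digits, ncol = 1L)
  varmat <- matrix(bases[digits + 1L], ncol = n)
  segs <- strsplit(design$backbone, "N", fixed = TRUE)[[1]]
  if (length(segs) < n + 1L) segs <- c(segs, rep("", n + 1L - length(segs)))
  pieces <- vector("list", 2L * n + 1L)
  for (j in seq_len(n)) {
    pieces[[2L * j - 1L]] <- segs[j]
    pieces[[2L * j]] <- varmat[, j]
  }
  pieces[[2L * n + 1L]] <- segs[n + 1L]
  core <- do.call(paste0, pieces)
  tibble(
    id = sprintf("spikein_%0*d", nchar(total - 1L), idx),
    variant = do.call(paste0, lapply(seq_len(n), function(j) varmat[, j])),
    core = core,
    sequence = paste0(design$flank5, core, design$flank3)
  )
}

#' Random transcript with a target GC fraction
#'
#' I.i.d. bases with `P(G) + P(C) = gc_prob`, split evenly within the GC
#' and AT pairs; reproducible under `seed`.
#'
#' @param length Transcript length in nt (>= 1).
#' @param gc_prob Target GC fraction in `[0, 1]`. Default 0.5.
#' @param seed Optional integer seed (local to this call).
#' @param id Transcript ID. Default `"synthetic_tx"`.
#' @return One-row transcript tibble (`id`, `sequence`, `length`).
#' @export
random_transcript <- function(length, gc_prob = 0.5, seed = NULL,
                              id = "synthetic_tx") {
  if (length < 1) abort("length must be >= 1")
  stopifnot(gc_prob >= 0, gc_prob <= 1)
  draw <- function() {
    paste0(sample(c("A", "T", "G", "C"), length, replace = TRUE,
                  prob = c((1 - gc_prob) / 2, (1 - gc_prob) / 2,
                           gc_prob / 2, gc_prob / 2)),
           collapse = "")
  }
  s <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(id = id, sequence = s, length = as.integer(length))
}

#' Multiplicative bias model for synthetic counts and fragments
#'
#' Specifies the generative biases injected into synthetic data:
#' linear multiplicative GC and MFE biases (centred so the mean multiplier
#' is ~1 and library size is roughly preserved), hexamer start preferences,
#' a Gaussian fragment-size law, and the count noise law. All multipliers
#' must stay positive; a fixed seed makes outputs byte-identical.
#'
#' Defaults encode the package's canonical biased-library conditions:
#' `beta_gc = 0.03` per GC unit and `beta_mfe = 0.02` per kcal/mol give a
#' roughly ±30% / ±20% count modulation over the GC and MFE ranges of
#' random 50-mers — moderate, realistic amplitudes. Set both to 0 for an
#' unbiased library.
#'
#' @param beta_gc GC bias slope: multiplier `1 + beta_gc * (gc - k/2)`.
#' @param beta_mfe MFE bias slope: multiplier
#'   `1 + beta_mfe * (mfe - mean(mfe))`.
#' @param gc_bias,mfe_bias Optional functions overriding the linear forms
#'   (take the gc / mfe vector, return multipliers).
#' @param hexamer_pref Optional named multiplier vector for fragment start
#'   hexamers.
#' @param size_mu,size_sigma Fragment length Gaussian (nt). Defaults 300, 30.
#' @param noise `"poisson"` (default), `"negbinom"`, or `"none"`
#'   (deterministic expected counts).
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param seed Integer seed. Default 1.
#' @return An object of class `bias_model`.
#' @export
bias_model <- function(beta_gc = 0.03, beta_mfe = 0.02, gc_bias = NULL,
                       mfe_bias = NULL, hexamer_pref = NULL, size_mu = 300,
                       size_sigma = 30, noise = c("poisson", "negbinom",
                                                  "none"),
                       dispersion = 0.1, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(size_mu > 0, size_sigma > 0, dispersion > 0)
  if (!is.null(hexamer_pref)) {
    stopifnot(!is.null(names(hexamer_pref)), all(hexamer_pref > 0))
  }
  structure(list(beta_gc = beta_gc, beta_mfe = beta_mfe, gc_bias = gc_bias,
                 mfe_bias = mfe_bias, hexamer_pref = hexamer_pref,
                 size_mu = size_mu, size_sigma = size_sigma, noise = noise,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "bias_model")
}

#' Simulate observed k-mer counts under a bias model
#'
#' Expected count of k-mer *i* is
#' `lambda_i = abundance * gc_mult(gc_i) * mfe_mult(mfe_i)`; `count_obs` is
#' drawn from the configured noise law with that mean. Seeded and
#' byte-identical at a fixed seed.
#'
#' @param kmers K-mer tibble; `mfe` must be populated when the MFE bias is
#'   active.
#' @param abundance True per-k-mer abundance `alpha` (> 0).
#' @param bias A [bias_model()].
#' @return `kmers` with `count_obs` filled; the expectation vector is
#'   attached as attribute `lambda`.
#' @export
simulate_counts <- function(kmers, abundance, bias = bias_model()) {
  stopifnot(inherits(bias, "bias_model"))
  if (!is.numeric(abundance) || abundance <= 0) {
    abort("abundance must be > 0")
  }
  k <- nchar(kmers$kmer[1])
  gcm <- if (!is.null(bias$gc_bias)) {
    bias$gc_bias(kmers$gc)
  } else {
    1 + bias$beta_gc * (kmers$gc - k / 2)
  }
  mfem <- if (!is.null(bias$mfe_bias)) {
    bias$mfe_bias(kmers$mfe)
  } else if (bias$beta_mfe != 0) {
    if (anyNA(kmers$mfe)) abort("mfe must be populated when the MFE bias is active")
    1 + bias$beta_mfe * (kmers$mfe - mean(kmers$mfe))
  } else {
    rep(1, nrow(kmers))
  }
  lambda <- abundance * gcm * mfem
  if (any(lambda <= 0)) {
    bad <- which(lambda <= 0)[1]
    abort(paste0("non-positive expected count for k-mer ", kmers$kmer[bad],
                 " (", kmers$transcript_id[bad], ":", kmers$start0[bad],
                 "); reduce the bias slopes"))
  }
  kmers$count_obs <- withr::with_seed(bias$seed, switch(
    bias$noise,
    poisson = as.numeric(rpois(length(lambda), lambda)),
    negbinom = as.numeric(rnbinom(length(lambda), mu = lambda,
                                  size = 1 / bias$dispersion)),
    none = lambda
  ))
  attr(kmers, "lambda") <- lambda
  kmers
}

#' Simulate paired-end fragments from a transcript
#'
#' Starts are uniform over the transcript; lengths are Gaussian
#' (`size_mu`, `size_sigma`), resampled until the fragment fits (and is at
#' least 6 nt); fragments are then acceptance-resampled in proportion to
#' the hexamer preference of their first six bases. Seeded.
#'
#' @param transcript One-row transcript tibble (or list with `id`,
#'   `sequence`); length must exceed `bias$size_mu`.
#' @param n_frags Number of fragments to generate.
#' @param bias A [bias_model()].
#' @return Fragment tibble: `transcript_id`, `start0`, `end0`, `length`,
#'   `first6` (0-based half-open coordinates).
#' @export
simulate_fragments <- function(transcript, n_frags, bias = bias_model()) {
  stopifnot(inherits(bias, "bias_model"))
  seqc <- transcript$sequence[1]
  id <- transcript$id[1]
  L <- nchar(seqc)
  if (L <= bias$size_mu) abort("transcript length must exceed size_mu")
  empty <- tibble(transcript_id = character(0), start0 = integer(0),
                  end0 = integer(0), length = integer(0),
                  first6 = character(0))
  if (n_frags == 0) return(empty)
  pref <- bias$hexamer_pref
  pmax_pref <- if (is.null(pref)) 1 else max(pref)
  withr::with_seed(bias$seed, {
    out_start <- integer(0)
    out_len <- integer(0)
    tries <- 0L
    while (length(out_start) < n_frags) {
      tries <- tries + 1L
      if (tries > 1000L) {
        abort("fragment simulation infeasible: acceptance rate too low")
      }
      m <- max(2L * (n_frags - length(out_start)), 100L)
      start0 <- sample.int(L - 6L + 1L, m, replace = TRUE) - 1L
      len <- as.integer(round(rnorm(m, bias$size_mu, bias$size_sigma)))
      ok <- len >= 6L & (start0 + len) <= L
      start0 <- start0[ok]; len <- len[ok]
      if (!is.null(pref) && length(start0) > 0L) {
        h <- substr(rep(seqc, length(start0)), start0 + 1L, start0 + 6L)
        p <- pref[h]
        p[is.na(p)] <- 1
        keep <- runif(length(start0)) < p / pmax_pref
        start0 <- start0[keep]; len <- len[keep]
      }
      out_start <- c(out_start, start0)
      out_len <- c(out_len, len)
    }
    out_start <- out_start[seq_len(n_frags)]
    out_len <- out_len[seq_len(n_frags)]
    tibble(
      transcript_id = id, start0 = out_start,
      end0 = out_start + out_len, length = out_len,
      first6 = substr(rep(seqc, n_frags), out_start + 1L, out_start + 6L)
    )
  })
}

#' Write spike-in or transcript tables as FASTA
#'
#' @param x Tibble with `id` and a sequence column (`sequence`).
#' @param path Output FASTA path.
#' @export
write_fasta <- function(x, path) {
  writeLines(paste0(">", x$id, "\n", x$sequence), path)
  invisible(path)
}
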