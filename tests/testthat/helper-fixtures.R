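# shared fixtures: everything is generated in code at test time

rand_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste0(sample(bases, n, replace = TRUE), collapse = "")
}

tx_tbl <- function(..., ids = NULL) {
  seqs <- c(...)
  tibble::tibble(
    id = ids %||% paste0("t", seq_along(seqs)),
    sequence = seqs, length = nchar(seqs)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cv <- function(x) stats::sd(x) / mean(x)

# minimal k-mer table straight from sequences (no transcript bookkeeping)
kmer_tbl <- function(seqs, mfe_vals = NA_real_, obs = 0) {
  tibble::tibble(
    transcript_id = "fixture", start0 = seq_along(seqs) - 1L,
    start1 = seq_along(seqs), kmer = seqs, gc = gc_count(seqs),
    mfe = mfe_vals, count_obs = obs, count_model = 1,
    count_cal = NA_real_, duplicated = FALSE
  )
}

# category table with the attributes categorize() would set
cat_tbl <- function(x, model, obs = model, n = 1L, key = "mfe",
                    precision = 0.1) {
  out <- tibble::tibble(category = x, n_kmers = as.integer(rep_len(n, length(x))),
                        agg_model = rep_len(model, length(x)),
                        agg_obs = rep_len(obs, length(x)))
  attr(out, "key") <- key
  attr(out, "precision") <- precision
  class(out) <- c("kcat_tbl", class(out))
  out
}

# independent MFE oracle: exhaustively enumerates every nested secondary
# structure (min hairpin loop 3) and scores it with the builtin pair
# energies; returns the minimum (<= 0, the open chain)
oracle_mfe <- function(seq, e_gc = -3, e_au = -2, e_gu = -1, min_loop = 3) {
  s <- strsplit(chartr("Tt", "UU", toupper(seq)), "")[[1]]
  pair_e <- function(a, b) {
    ab <- paste0(a, b)
    if (ab %in% c("GC", "CG")) return(e_gc)
    if (ab %in% c("AU", "UA")) return(e_au)
    if (ab %in% c("GU", "UG")) return(e_gu)
    NA_real_
  }
  structs <- function(i, j) {
    if (i > j || j - i < min_loop + 1) return(list(list()))
    out <- structs(i + 1, j)                     # i unpaired
    for (l in seq(i + min_loop + 1, j)) {
      e <- pair_e(s[i], s[l])
      if (is.na(e)) next
      left <- structs(i + 1, l - 1)
      right <- structs(l + 1, j)
      for (s1 in left) for (s2 in right) {
        out <- c(out, list(c(list(c(i, l, e)), s1, s2)))
      }
    }
    out
  }
  all_structs <- structs(1, length(s))
  scores <- vapply(all_structs, function(st) {
    if (length(st) == 0) 0 else sum(vapply(st, `[`, numeric(1), 3))
  }, numeric(1))
  min(0, min(scores))
}

# spike-in k-mer table (one row per enumerated 50-mer core), cached per run
spikein_kmers <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- enumerate_spikeins(spikein_design())
      cache <<- extract_kmers(tx_tbl(sp$core, ids = sp$id), k = 50)
    }
    cache
  }
})

# manual tricube local-linear regression at one point (LOESS oracle)
tricube_local_linear <- function(x, y, x0, span) {
  n <- length(x)
  q <- min(n, ceiling(span * n))
  d <- abs(x - x0)
  dmax <- sort(d, partial = q)[q]
  w <- ifelse(d <= dmax, (1 - pmin(d / dmax, 1)^3)^3, 0)
  fit <- stats::lm(y ~ x, weights = w)
  unname(stats::predict(fit, data.frame(x = x0)))
}
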