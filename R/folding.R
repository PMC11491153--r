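#' Secondary-structure folding engines
#'
#' A fold engine turns a nucleotide sequence into the minimum free energy
#' (MFE, kcal/mol) of its secondary structure. Two engines are provided:
#'
#' * `"builtin"` — a Nussinov-style dynamic program that minimises summed
#'   base-pair energies (GC −3.0, AU −2.0, GU −1.0 kcal/mol, minimum hairpin
#'   loop of 3 unpaired bases, nested structures only). Deterministic, fully
#'   self-contained, and reproduces the key qualitative property the GSB
#'   framework relies on: MFE anticorrelates with GC content.
#' * `"vienna"` — an adapter to the `RNAfold` executable (nearest-neighbor
#'   thermodynamics at `temperature` °C) when it is on the `PATH`.
#'
#' MFE values are rounded to `precision` kcal/mol; this rounding defines
#' category identity downstream (see [categorize()]). The open chain at
#' energy 0 is always admissible, so MFE ≤ 0 for every sequence.
#'
#' @param name `"builtin"` or `"vienna"`.
#' @param temperature Folding temperature in °C (vienna engine only).
#'   Default 37.
#' @param precision Rounding quantum in kcal/mol. Default 0.1.
#' @return An object of class `fold_engine`.
#' @export
#' @examples
#' eng <- fold_engine()
#' mfe("GGGGAAAACCCC", eng)  # 4 GC pairs: -12.0
fold_engine <- function(name = c("builtin", "vienna"), temperature = 37,
                        precision = 0.1) {
  name <- match.arg(name)
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.numeric(precision), precision > 0)
  if (name == "vienna" && !vienna_available()) {
    abort("RNAfold executable not found on PATH; use fold_engine(\"builtin\")")
  }
  structure(
    list(name = name, temperature = temperature, precision = precision,
         # builtin pair energies (kcal/mol) and minimum hairpin loop
         e_gc = -3.0, e_au = -2.0, e_gu = -1.0, min_loop = 3L),
    class = "fold_engine"
  )
}

vienna_available <- function() nzchar(Sys.which("RNAfold"))

#' @export
print.fold_engine <- function(x, ...) {
  cat("<fold_engine> ", x$name, " (T = ", x$temperature, " °C, precision ",
      x$precision, " kcal/mol)\n", sep = "")
  invisible(x)
}

#' Minimum free energy of nucleotide sequences
#'
#' Vectorised MFE computation. `T` is treated as `U`; duplicated sequences
#' are folded once (per-call cache) and the number of distinct engine
#' evaluations is attached as attribute `n_engine_calls`. A sequence with no
#' admissible base pair returns exactly 0.
#'
#' @param seqs Character vector of sequences over `{A,C,G,T,U}`
#'   (case-insensitive).
#' @param engine A [fold_engine()]. Default: builtin.
#' @return Numeric vector of MFEs (kcal/mol), rounded to `engine$precision`,
#'   in input order.
#' @export
mfe <- function(seqs, engine = fold_engine()) {
  stopifnot(inherits(engine, "fold_engine"))
  seqs <- as.character(seqs)
  if (length(seqs) == 0L) {
    return(structure(numeric(0), n_engine_calls = 0L))
  }
  if (any(!nzchar(seqs))) abort("empty sequence")
  rna <- chartr("Tt", "Uu", toupper(seqs))
  bad <- grepl("[^ACGU]", rna)
  if (any(bad)) {
    abort(paste0("unsupported characters in sequence(s) at index ",
                 paste0(head(which(bad), 5L), collapse = ",")))
  }
  uniq <- unique(rna)
  vals <- switch(engine$name,
    builtin = nussinov_mfe(uniq, engine$e_gc, engine$e_au, engine$e_gu,
                           engine$min_loop),
    vienna = vienna_mfe(uniq, engine$temperature)
  )
  vals <- round(vals / engine$precision) * engine$precision
  vals[vals == 0] <- 0  # normalise -0.0
  out <- vals[match(rna, uniq)]
  attr(out, "n_engine_calls") <- length(uniq)
  out
}

# RNAfold adapter: one call per batch, `--noPS`, energies parsed from the
# "( -5.40)" suffix of each structure line.
vienna_mfe <- function(rna, temperature) {
  res <- suppressWarnings(system2(
    "RNAfold", args = c("--noPS", paste0("--temp=", temperature)),
    input = rna, stdout = TRUE, stderr = FALSE
  ))
  lines <- res[grepl("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", res)]
  if (length(lines) != length(rna)) {
    abort("RNAfold output could not be parsed")
  }
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", lines))
}

#' Attach MFE values to a k-mer table
#'
#' @param kmers K-mer tibble from [extract_kmers()].
#' @param engine A [fold_engine()].
#' @return `kmers` with the `mfe` column filled (duplicated k-mers folded
#'   once).
#' @export
add_mfe <- function(kmers, engine = fold_engine()) {
  kmers$mfe <- as.numeric(mfe(kmers$kmer, engine))
  kmers
}
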