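#' Free Gaussian fit of category aggregates
#'
#' Fits \eqn{y_c = A \exp(-(x_c-\mu)^2 / (2\sigma^2))} to the per-category
#' aggregates of a [categorize()] table by nonlinear least squares (one point
#' per category, unweighted by default). For modeling aggregates this
#' predetermines the benchmark mean and SD that the fixed-parameter fits
#' then lock.
#'
#' Initialisation uses the count-weighted mean and SD of the category values
#' and the maximum aggregate; on non-convergence a small restart grid around
#' those values is tried, and the best parameters found are carried in the
#' error if all restarts fail.
#'
#' @param table A `kcat_tbl` from [categorize()] (or any data frame with
#'   columns `category`, `n_kmers` and the chosen aggregate).
#' @param which Fit the `"model"` (default) or `"obs"` aggregates.
#' @param weighted Weight categories by `n_kmers` in the least squares.
#'   Default `FALSE` (each category is one point).
#' @param r2_floor Modeling fits with \eqn{R^2} below this are flagged
#'   unreliable (warning). Default 0.9.
#' @return An object of class `gauss_fit`: amplitude `A`, mean `mu`, SD
#'   `sigma` (> 0), `r2`, logical `reliable` and `degenerate`, and `data`
#'   (tibble `x`, `n_kmers`, `y`, `fitted`, `residual`). Constant aggregates
#'   give a degenerate fit (no parameters) with a warning.
#' @seealso [fit_amplitude_fixed()], [fit_cdf_amplitude()], [tidy.gauss_fit()]
#' @export
#' @examples
#' x <- 0:8
#' tab <- tibble::tibble(category = x, n_kmers = 1L,
#'                       agg_model = 100 * exp(-(x - 4)^2 / 8))
#' glance(fit_gaussian_free(tab))
fit_gaussian_free <- function(table, which = c("model", "obs"),
                              weighted = FALSE, r2_floor = 0.9) {
  which <- match.arg(which)
  y <- if (which == "model") table$agg_model else table$agg_obs
  x <- table$category
  if (sum(y > 0) < 4L) abort("need at least 4 categories with positive aggregate")
  w <- if (weighted) table$n_kmers else rep(1, length(x))
  sstot <- sum((y - mean(y))^2)
  base <- list(A = NA_real_, mu = NA_real_, sigma = NA_real_, r2 = NA_real_,
               which = which, key = attr(table, "key"), weighted = weighted,
               degenerate = FALSE, reliable = FALSE,
               data = tibble(x = x, n_kmers = table$n_kmers, y = y,
                             fitted = NA_real_, residual = NA_real_))
  if (sstot == 0) {
    warn("constant aggregates: Gaussian fit is degenerate, no parameters")
    base$degenerate <- TRUE
    return(structure(base, class = "gauss_fit"))
  }
  mu0 <- weighted.mean(x, w = pmax(y, 0))
  sigma0 <- sqrt(weighted.mean((x - mu0)^2, w = pmax(y, 0)))
  if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- sd(x)
  A0 <- max(y)
  starts <- tidyr::expand_grid(mu = mu0 + c(0, -1, 1) * sigma0,
                               sigma = sigma0 * c(1, 0.5, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
        start = list(A = A0, mu = starts$mu[i], sigma = starts$sigma[i]),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    p <- as.list(coef(fit))
    p$sigma <- abs(p$sigma)
    fitted <- p$A * exp(-(x - p$mu)^2 / (2 * p$sigma^2))
    r2 <- 1 - sum((y - fitted)^2) / sstot
    if (is.null(best) || r2 > best$r2) {
      best <- c(p, list(r2 = r2, fitted = fitted))
    }
    if (best$r2 > 1 - 1e-12) break
  }
  if (is.null(best)) {
    abort("Gaussian fit did not converge from any restart")
  }
  out <- base
  out$A <- best$A; out$mu <- best$mu; out$sigma <- best$sigma
  out$r2 <- best$r2
  out$data$fitted <- best$fitted
  out$data$residual <- out$data$y - best$fitted
  out$reliable <- best$r2 >= r2_floor
  if (which == "model" && !out$reliable) {
    warn(paste0("modeling Gaussian fit R^2 = ", signif(best$r2, 4),
                " below floor ", r2_floor, "; flagged unreliable"))
  }
  structure(out, class = "gauss_fit")
}

#' Free Gaussian-CDF fit of cumulative category aggregates
#'
#' Fits \eqn{Y_c = A\,\Phi((x_c-\mu)/\sigma)} to the cumulative aggregates
#' over ascending category values. Used to derive CDF benchmark parameters
#' from modeling data when refitting is preferred over reusing the PDF-fit
#' parameters.
#'
#' @inheritParams fit_gaussian_free
#' @param continuity Evaluate \eqn{\Phi} at the category upper edge (half
#'   the median spacing), as in [fit_cdf_amplitude()]. Default `TRUE`.
#' @return A `gauss_fit` (with `mode = "cdf"` recorded).
#' @export
fit_gaussian_cdf_free <- function(table, which = c("model", "obs"),
                                  weighted = FALSE, r2_floor = 0.9,
                                  continuity = TRUE) {
  which <- match.arg(which)
  stopifnot(!is.unsorted(table$category, strictly = TRUE))
  y <- cumsum(if (which == "model") table$agg_model else table$agg_obs)
  # evaluate at the category upper edge (see fit_cdf_amplitude) so the
  # fitted mu is on the same scale as the PDF fit's
  x <- table$category +
    if (continuity && nrow(table) > 1L) median(diff(table$category)) / 2 else 0
  if (length(x) < 4L) abort("need at least 4 categories")
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) abort("constant cumulative aggregates")
  mu0 <- x[which.min(abs(y - max(y) / 2))]
  sigma0 <- max(diff(range(x)) / 4, 1e-6)
  fit <- minpack.lm::nlsLM(
    y ~ A * pnorm((x - mu) / sigma),
    start = list(A = max(y), mu = mu0, sigma = sigma0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- as.list(coef(fit)); p$sigma <- abs(p$sigma)
  fitted <- p$A * pnorm((x - p$mu) / p$sigma)
  r2 <- 1 - sum((y - fitted)^2) / sstot
  structure(list(
    A = p$A, mu = p$mu, sigma = p$sigma, r2 = r2, which = which,
    key = attr(table, "key"), weighted = weighted, mode = "cdf",
    degenerate = FALSE, reliable = r2 >= r2_floor,
    data = tibble(x = x, n_kmers = table$n_kmers, y = y, fitted = fitted,
                  residual = y - fitted)
  ), class = "gauss_fit")
}

#' Fixed-parameter amplitude fit of observed aggregates
#'
#' The self-benchmarking step: with the mean and SD locked to the
#' modeling-data values, only the amplitude is fitted to the observed
#' aggregates. With \eqn{g_c = \exp(-(x_c-\mu)^2/(2\sigma^2))} the
#' least-squares optimum has the closed form
#' \eqn{A^* = \sum_c w_c y_c g_c / \sum_c w_c g_c^2}. Predicted counts
#' \eqn{A^* g_c} are the unbiased benchmark per category; residuals are
#' reported, never clipped.
#'
#' @param table A `kcat_tbl` with observed aggregates.
#' @param mu,sigma Fixed Gaussian parameters from the modeling fit
#'   (`sigma > 0`), or a `gauss_fit` passed as `mu` with `sigma` missing.
#' @param weighted Weight categories by `n_kmers`. Default `FALSE`.
#' @param drop_zero_obs Drop categories with zero observed aggregate from
#'   the amplitude estimate (they are retained by default: zeros inform the
#'   amplitude).
#' @return An object of class `amp_fit`: `amplitude`, fixed `mu`, `sigma`,
#'   `r2`, `mode = "pdf"`, and `data` (tibble `x`, `n_kmers`, `y`,
#'   `predicted`, `residual`).
#' @export
#' @examples
#' tab <- tibble::tibble(category = c(-2, 0, 2), n_kmers = 1L,
#'                       agg_model = 1, agg_obs = c(2, 4, 2))
#' # g = (exp(-2), 1, exp(-2)) at mu = 0, sigma = 1
#' fit_amplitude_fixed(tab, mu = 0, sigma = sqrt(2))$amplitude
fit_amplitude_fixed <- function(table, mu, sigma, weighted = FALSE,
                                drop_zero_obs = FALSE) {
  if (inherits(mu, "gauss_fit")) {
    sigma <- mu$sigma
    mu <- mu$mu
  }
  stopifnot(is.numeric(mu), is.numeric(sigma))
  if (sigma <= 0) abort("sigma must be > 0")
  x <- table$category
  y <- table$agg_obs
  g <- exp(-(x - mu)^2 / (2 * sigma^2))
  if (all(g == 0)) {
    abort("all Gaussian weights underflow to 0: (mu, sigma) inconsistent with categories")
  }
  w <- if (weighted) table$n_kmers else rep(1, length(x))
  use <- if (drop_zero_obs) y > 0 else rep(TRUE, length(y))
  A <- sum(w[use] * y[use] * g[use]) / sum(w[use] * g[use]^2)
  predicted <- A * g
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sum((y - predicted)^2) / sstot else NA_real_
  structure(list(
    amplitude = A, mu = mu, sigma = sigma, mode = "pdf",
    key = attr(table, "key"), precision = attr(table, "precision"),
    weighted = weighted, r2 = r2,
    data = tibble(x = x, n_kmers = table$n_kmers, y = y,
                  predicted = predicted, residual = y - predicted)
  ), class = "amp_fit")
}

#' Fixed-parameter Gaussian-CDF amplitude: the abundance estimate
#'
#' Cumulative observed aggregates \eqn{Y_c} over ascending category values
#' (most stable, most negative MFE first) are fitted by
#' \eqn{A\,\Phi((x_c-\mu)/\sigma)} with \eqn{(\mu,\sigma)} fixed from the
#' modeling data; the closed-form amplitude
#' \eqn{A^* = \sum Y_c \Phi_c / \sum \Phi_c^2} is the bias-corrected
#' cumulative count — the abundance estimate for the region.
#'
#' The cumulative aggregate at a category value includes that whole
#' category, so it estimates the continuous CDF at the category's upper
#' edge; by default a half-spacing continuity correction (`h/2`, with `h`
#' the median category spacing) is applied when evaluating \eqn{\Phi},
#' which removes the systematic amplitude overestimate this discretization
#' otherwise causes.
#'
#' @inheritParams fit_amplitude_fixed
#' @param continuity Apply the half-spacing continuity correction.
#'   Default `TRUE`.
#' @return An `amp_fit` with `mode = "cdf"`; `amplitude` is the abundance
#'   estimate, `data$y` holds the cumulative observed aggregates.
#' @export
fit_cdf_amplitude <- function(table, mu, sigma, weighted = FALSE,
                              continuity = TRUE) {
  if (inherits(mu, "gauss_fit")) {
    sigma <- mu$sigma
    mu <- mu$mu
  }
  if (sigma <= 0) abort("sigma must be > 0")
  if (is.unsorted(table$category, strictly = TRUE)) {
    abort("categories must be strictly ascending for the CDF fit")
  }
  x <- table$category
  Y <- cumsum(table$agg_obs)
  shift <- if (continuity && length(x) > 1L) median(diff(x)) / 2 else 0
  phi <- pnorm((x + shift - mu) / sigma)
  w <- if (weighted) table$n_kmers else rep(1, length(x))
  A <- sum(w * Y * phi) / sum(w * phi^2)
  predicted <- A * phi
  sstot <- sum((Y - mean(Y))^2)
  structure(list(
    amplitude = A, mu = mu, sigma = sigma, mode = "cdf",
    key = attr(table, "key"), precision = attr(table, "precision"),
    weighted = weighted,
    r2 = if (sstot > 0) 1 - sum((Y - predicted)^2) / sstot else NA_real_,
    data = tibble(x = x, n_kmers = table$n_kmers, y = Y,
                  predicted = predicted, residual = Y - predicted)
  ), class = "amp_fit")
}

#' Redistribute category predictions to single k-mers
#'
#' The per-category benchmark predictions are averaged over the k-mers of
#' each category: a k-mer in category `c` receives
#' `count_cal = predicted_c / n_kmers(c)`. This corrects every k-mer to the
#' unbiased per-k-mer expectation of its category. The operation is
#' idempotent: calibrating already-calibrated counts reproduces them.
#'
#' @param kmers K-mer tibble (with `mfe` populated when the fit is
#'   MFE-keyed).
#' @param fit An `amp_fit` from [fit_amplitude_fixed()], or any object whose
#'   `$data` has columns `x`, `n_kmers`, `predicted` and whose `$key` /
#'   `$precision` describe the categorization (e.g.
#'   [smooth_category_counts()] output).
#' @return `kmers` with `count_cal` filled and `category_id` set; attribute
#'   `summary` holds mean, SD and CV of `count_cal` and the CV of
#'   `count_obs` for comparison.
#' @export
calibrate_kmers <- function(kmers, fit) {
  key <- fit$key %||% "mfe"
  precision <- fit$precision %||% 0.1
  val <- if (key == "gc") {
    as.numeric(kmers$gc)
  } else {
    if (anyNA(kmers$mfe)) abort("mfe column must be populated")
    round(kmers$mfe / precision) * precision
  }
  idx <- match(val, fit$data$x)
  if (anyNA(idx)) {
    abort("k-mer table contains categories absent from the fit; refit on this table")
  }
  kmers$category_id <- paste0(key, ":", fit$data$x[idx])
  kmers$count_cal <- fit$data$predicted[idx] / fit$data$n_kmers[idx]
  attr(kmers, "summary") <- tibble(
    mean_cal = mean(kmers$count_cal), sd_cal = sd(kmers$count_cal),
    cv_cal = cv(kmers$count_cal), cv_obs = cv(kmers$count_obs)
  )
  kmers
}

#' Normalize an abundance amplitude to RPKM / TPM
#'
#' @param amplitude CDF amplitude(s): bias-corrected cumulative counts, one
#'   per region.
#' @param region_length_nt Region length(s) in nt (> 0).
#' @param library_total Total mapped reads (or k-mer matches) in the
#'   library (> 0).
#' @return A tibble with columns `amplitude`, `region_length_nt`, `rpkm`
#'   and `tpm` (TPM computed across the supplied set; sums to 1e6).
#' @export
#' @examples
#' normalize_abundance(1000, 1000, 1e6)  # RPKM 1000
normalize_abundance <- function(amplitude, region_length_nt, library_total) {
  if (any(region_length_nt <= 0)) abort("region_length_nt must be > 0")
  if (length(library_total) != 1L || library_total <= 0) {
    abort("library_total must be a single positive number")
  }
  rate <- amplitude / region_length_nt
  tibble(
    amplitude = amplitude,
    region_length_nt = region_length_nt,
    rpkm = amplitude / (region_length_nt / 1e3) / (library_total / 1e6),
    tpm = rate / sum(rate) * 1e6
  )
}
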