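#' @export
print.gauss_fit <- function(x, ...) {
  mode <- x$mode %||% "pdf"
  cat("<gauss_fit> free Gaussian ", if (mode == "cdf") "CDF " else "",
      "fit of ", x$which, " aggregates (key = ", x$key %||% "?", ")\n",
      sep = "")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate (constant aggregates); no parameters\n")
  } else {
    cat(sprintf("  A = %.4g, mu = %.4g, sigma = %.4g, R^2 = %.4f%s\n",
                x$A, x$mu, x$sigma, x$r2,
                if (!x$reliable) "  [unreliable]" else ""))
  }
  invisible(x)
}

#' @export
print.amp_fit <- function(x, ...) {
  cat("<amp_fit> fixed-parameter ", toupper(x$mode), " amplitude fit",
      " (key = ", x$key %||% "?", ")\n", sep = "")
  cat(sprintf("  amplitude = %.6g at fixed mu = %.4g, sigma = %.4g (R^2 = %.4f)\n",
              x$amplitude, x$mu, x$sigma, x$r2))
  invisible(x)
}

#' @export
print.gsb_run <- function(x, ...) {
  cat("<gsb_run> ", x$config$key, "-GSB calibration of ", nrow(x$kmers),
      " k-mers in ", nrow(x$categories), " categories\n", sep = "")
  cat(sprintf("  modeling fit: mu = %.4g, sigma = %.4g, R^2 = %.4f\n",
              x$model_fit$mu, x$model_fit$sigma, x$model_fit$r2))
  cat(sprintf("  amplitude = %.6g;  CV %.4f -> %.4f\n",
              x$amp_fit$amplitude, x$cv_before, x$cv_after))
  invisible(x)
}

#' @export
print.gsb_comparison <- function(x, ...) {
  cat("<gsb_comparison> ", nrow(x$kmers), " k-mers; per-method CV:\n",
      sep = "")
  print(x$summary)
  invisible(x)
}

#' Tidy a Gaussian fit into one row per parameter
#'
#' @param x A `gauss_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`.
#' @export
tidy.gauss_fit <- function(x, ...) {
  tibble(term = c("A", "mu", "sigma"),
         estimate = c(x$A, x$mu, x$sigma))
}

#' One-row fit summary of a Gaussian fit
#'
#' @param x A `gauss_fit`.
#' @param ... Unused.
#' @return Tibble `A`, `mu`, `sigma`, `r2`, `n_categories`, `reliable`,
#'   `degenerate`.
#' @export
glance.gauss_fit <- function(x, ...) {
  tibble(A = x$A, mu = x$mu, sigma = x$sigma, r2 = x$r2,
         n_categories = nrow(x$data), reliable = x$reliable,
         degenerate = x$degenerate)
}

#' @rdname tidy.gauss_fit
#' @export
tidy.amp_fit <- function(x, ...) {
  tibble(term = c("amplitude", "mu", "sigma"),
         estimate = c(x$amplitude, x$mu, x$sigma))
}

#' @rdname glance.gauss_fit
#' @export
glance.amp_fit <- function(x, ...) {
  tibble(amplitude = x$amplitude, mu = x$mu, sigma = x$sigma, r2 = x$r2,
         mode = x$mode, n_categories = nrow(x$data))
}

#' @rdname glance.gauss_fit
#' @export
glance.gsb_run <- function(x, ...) {
  tibble(key = x$config$key, n_kmers = nrow(x$kmers),
         n_categories = nrow(x$categories),
         mu = x$model_fit$mu, sigma = x$model_fit$sigma,
         model_r2 = x$model_fit$r2, amplitude = x$amp_fit$amplitude,
         cv_before = x$cv_before, cv_after = x$cv_after)
}

#' Plot category aggregates
#'
#' Observed and modeling aggregates against the category value.
#'
#' @param object A `kcat_tbl`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kcat_tbl <- function(object, ...) {
  d <- tidyr::pivot_longer(
    as_tibble(object)[, c("category", "agg_model", "agg_obs")],
    cols = c("agg_model", "agg_obs"),
    names_to = "series", values_to = "aggregate"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$aggregate,
                                  colour = .data$series)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = paste0("category (", attr(object, "key"), ")"),
                  y = "aggregate count", colour = NULL)
}

#' Plot a Gaussian or amplitude fit over its category data
#'
#' @param object A `gauss_fit` or `amp_fit`.
#' @param ... Unused.
#' @return A ggplot of aggregates (points) and the fitted curve (line).
#' @export
autoplot.gauss_fit <- function(object, ...) {
  fitted_col <- if ("fitted" %in% names(object$data)) "fitted" else "predicted"
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y)) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[fitted_col]]),
                       colour = "firebrick") +
    ggplot2::labs(x = paste0("category (", object$key %||% "value", ")"),
                  y = "aggregate count")
}

#' @rdname autoplot.gauss_fit
#' @export
autoplot.amp_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                       colour = "firebrick") +
    ggplot2::labs(
      x = paste0("category (", object$key %||% "value", ")"),
      y = if (object$mode == "cdf") "cumulative aggregate" else "aggregate"
    )
}

#' Per-k-mer counts before and after calibration
#'
#' @param object A `gsb_run`.
#' @param ... Unused.
#' @return A ggplot of observed and calibrated counts along the transcript.
#' @export
autoplot.gsb_run <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$kmers[, c("start0", "count_obs", "count_cal")],
    cols = c("count_obs", "count_cal"),
    names_to = "series", values_to = "count"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start0, y = .data$count,
                                  colour = .data$series)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "k-mer start (0-based)", y = "count", colour = NULL)
}

#' Per-method CV summary plot of a comparison
#'
#' @param object A `gsb_comparison`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-method coefficients of variation.
#' @export
autoplot.gsb_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = stats::reorder(.data$method, .data$cv),
                               y = .data$cv)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "per-k-mer CV")
}
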