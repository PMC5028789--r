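#' Smooth depth trends and correlation matrices
#'
#' Each per-station metric is regressed on station depth with a penalized
#' cubic regression spline (a Gaussian generalized additive model, smoothing
#' parameter chosen by restricted maximum likelihood). The fitted object
#' carries the standard smooth-term summaries — effective degrees of freedom
#' (the flexibility actually used), an approximate F statistic and p-value,
#' and adjusted R-squared — plus a fitted curve with standard errors over
#' the observed depth range.
#'
#' @name depth_trends
NULL

#' Fit a smooth depth trend to one station-level metric
#'
#' @param data Data frame with one row per station.
#' @param metric Name of the response column (string).
#' @param depth_col Name of the depth column (default \code{"depth_m"}).
#' @param basis_dim Spline basis dimension k (default 10).
#' @param grid_length Length of the prediction grid (default 200).
#' @return A \code{depth_trend} object; see [tidy.depth_trend()],
#'   [glance.depth_trend()], [autoplot.depth_trend()].
#' @export
fit_depth_smoother <- function(data, metric, depth_col = "depth_m",
                               basis_dim = 10, grid_length = 200) {
  df <- as_tibble(data)
  for (col in c(metric, depth_col)) {
    if (!col %in% names(df)) abort(paste0("Column not found: ", col))
  }
  d <- tibble(depth = df[[depth_col]], y = df[[metric]])
  n_missing <- sum(!complete.cases(d))
  if (n_missing > 0) {
    inform(sprintf("Dropped %d station(s) with missing %s or depth.",
                   n_missing, metric))
    d <- d[complete.cases(d), ]
  }
  if (nrow(d) < 8) abort("Need at least 8 complete (depth, value) pairs.")
  if (length(unique(d$depth)) < 2) abort("Depths must not all be equal.")
  k <- min(basis_dim, length(unique(d$depth)) - 1)
  fit <- mgcv::gam(y ~ s(depth, k = k, bs = "cr"), data = d,
                   method = "REML")
  smry <- summary(fit)
  grid <- tibble(depth = seq(min(d$depth), max(d$depth),
                             length.out = grid_length))
  pred <- predict(fit, newdata = grid, se.fit = TRUE)
  structure(
    list(metric = metric, fit = fit, n = nrow(d), n_dropped = n_missing,
         edf = unname(smry$edf[1]), f_stat = unname(smry$s.table[1, "F"]),
         p_value = unname(smry$s.table[1, "p-value"]),
         r2 = unname(smry$r.sq),
         curve = tibble(depth_m = grid$depth, fitted = as.numeric(pred$fit),
                        se = as.numeric(pred$se.fit))),
    class = "depth_trend")
}

#' @export
print.depth_trend <- function(x, ...) {
  cat(sprintf("<depth_trend> %s ~ s(depth), n = %d\n", x$metric, x$n))
  cat(sprintf("  F = %.2f, e.d.f. = %.2f, adj. R^2 = %.3f, p = %.3g\n",
              x$f_stat, x$edf, x$r2, x$p_value))
  invisible(x)
}

#' Tidy a fitted depth trend
#'
#' @param x A \code{depth_trend} object.
#' @param ... Unused.
#' @return One row per grid point of the fitted curve: \code{metric},
#'   \code{depth_m}, \code{fitted}, \code{se}.
#' @exportS3Method generics::tidy
tidy.depth_trend <- function(x, ...) {
  mutate(x$curve, metric = x$metric, .before = 1)
}

#' One-row summary of a fitted depth trend
#'
#' @param x A \code{depth_trend} object.
#' @param ... Unused.
#' @return A tibble with \code{metric}, \code{f_stat}, \code{edf},
#'   \code{r2}, \code{p_value}, \code{n}.
#' @exportS3Method generics::glance
glance.depth_trend <- function(x, ...) {
  tibble(metric = x$metric, f_stat = x$f_stat, edf = x$edf, r2 = x$r2,
         p_value = x$p_value, n = x$n)
}

#' Plot a fitted depth trend
#'
#' @param object A \code{depth_trend} object.
#' @param ... Unused.
#' @return A ggplot: observations, fitted curve, +/- 2 SE ribbon.
#' @exportS3Method ggplot2::autoplot
autoplot.depth_trend <- function(object, ...) {
  obs <- tibble(depth_m = object$fit$model$depth, y = object$fit$model$y)
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$depth_m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fitted - 2 * .data$se,
                                      ymax = .data$fitted + 2 * .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$y), alpha = 0.6) +
    ggplot2::labs(x = "Depth (m)", y = object$metric) +
    ggplot2::theme_minimal()
}

#' Fit depth trends to several metrics at once
#'
#' @param data One row per station, with a depth column and the metric
#'   columns.
#' @param metrics Character vector of metric column names.
#' @inheritParams fit_depth_smoother
#' @return A tibble with one row per metric (the [glance.depth_trend()]
#'   columns) and a list-column \code{trend} holding the fitted objects.
#' @export
fit_depth_trends <- function(data, metrics, depth_col = "depth_m",
                             basis_dim = 10) {
  fits <- purrr::map(metrics, function(mt)
    fit_depth_smoother(data, mt, depth_col = depth_col,
                       basis_dim = basis_dim))
  purrr::map(fits, glance) |>
    list_rbind() |>
    mutate(trend = fits)
}

#' Pairwise Pearson correlations with pairwise-complete observations
#'
#' @param data Data frame of numeric variables (non-numeric columns are
#'   dropped with a message).
#' @param min_pairs Minimum number of complete observation pairs for a
#'   coefficient to be reported (default 3); sparser pairs get \code{NA}
#'   with a warning.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlations <- function(data, min_pairs = 3) {
  df <- as_tibble(data)
  num <- vapply(df, is.numeric, logical(1))
  if (any(!num)) {
    inform(paste0("Dropping non-numeric column(s): ",
                  paste(names(df)[!num], collapse = ", ")))
    df <- df[num]
  }
  m <- as.matrix(df)
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  counts <- crossprod(!is.na(m))
  sparse <- counts < min_pairs
  diag(sparse) <- FALSE
  if (any(sparse)) {
    warn(sprintf("%d variable pair(s) with fewer than %d complete observations: set to NA.",
                 sum(sparse) / 2, min_pairs))
    r[sparse] <- NA_real_
  }
  diag(r) <- 1
  r
}
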