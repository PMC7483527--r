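#' Pearson product-moment correlation
#'
#' Pairwise-complete product-moment correlation with explicit degenerate
#' input handling: fewer than 3 complete pairs or a constant input is an
#' error rather than `NA`.
#'
#' @param x,y numeric vectors of equal length.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  stats::cor(x, y)
}

#' Partial correlation via residualization
#'
#' The correlation between `x` and `y` after removing the linear influence
#' of the control variables from both, i.e. the Pearson correlation of the
#' residuals from least-squares regressions of `x` and `y` on the controls
#' (with intercept). Rows with any missing value are dropped listwise.
#' With no controls this is exactly [pearson_r()].
#'
#' @param x,y numeric vectors.
#' @param controls numeric matrix/data frame of control variables (may be
#'   `NULL` or zero-column).
#' @return The partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  if (is.null(controls)) controls <- matrix(numeric(0), nrow = length(x))
  controls <- as.matrix(controls)
  stopifnot(length(x) == length(y), nrow(controls) == length(x))
  ok <- stats::complete.cases(x, y, controls)
  x <- x[ok]; y <- y[ok]
  controls <- controls[ok, , drop = FALSE]
  k <- ncol(controls)
  if (length(x) <= k + 2L) {
    stop("need more than ", k + 2L, " complete rows for ", k, " controls")
  }
  if (k == 0L) return(pearson_r(x, y))
  storage.mode(controls) <- "double"
  X <- cbind(`(intercept)` = 1, controls)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("rank-deficient controls: ", paste(drop, collapse = ", "))
  }
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) stop("constant input")
  stats::cor(rx, ry)
}

#' Bias-corrected and accelerated (BCa) bootstrap for a scalar statistic
#'
#' Resamples rows of `data` with replacement, recomputes `statistic` on
#' each resample, and returns the bootstrap standard error plus the BCa
#' confidence interval: the bias-correction factor `z0` comes from the
#' fraction of replicates below the point estimate, the acceleration `a`
#' from the jackknife skewness formula, and the interval endpoints are
#' order statistics of the bootstrap distribution at the adjusted levels.
#' Resamples on which the statistic is undefined (error or non-finite) are
#' redrawn and counted; if more than 1% of replicates need redrawing the
#' call fails. Results are deterministic given `seed`.
#'
#' @param statistic function `(data, index_vector) -> scalar`, the same
#'   contract as the `boot` package.
#' @param data a data frame or matrix whose rows are the resampling units.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param conf confidence level.
#' @return List: `estimate`, `se`, `ci_low`, `ci_high`, `n`, `n_boot`,
#'   `n_redrawn`, `conf`, `seed`.
#' @export
bca_bootstrap <- function(statistic, data, n_boot = 2000L, seed = NULL,
                          conf = 0.95) {
  n <- nrow(data)
  stopifnot(is.function(statistic), n >= 3L, n_boot >= 100L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  t0 <- statistic(data, seq_len(n))
  if (!is.finite(t0)) stop("statistic undefined on the full sample")

  max_redraw <- ceiling(0.01 * n_boot)
  boot_stat <- numeric(n_boot)
  n_redrawn <- 0L
  safe <- function(idx) {
    tryCatch(statistic(data, idx), error = function(e) NA_real_)
  }
  for (b in seq_len(n_boot)) {
    repeat {
      v <- safe(sample.int(n, n, replace = TRUE))
      if (is.finite(v)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max_redraw) {
        stop("statistic undefined on more than 1% of resamples")
      }
    }
    boot_stat[b] <- v
  }

  se <- stats::sd(boot_stat)
  prop <- (sum(boot_stat < t0) + 0.5 * sum(boot_stat == t0)) / n_boot
  if (prop <= 0 || prop >= 1) {
    stop("bootstrap distribution entirely on one side of the estimate")
  }
  z0 <- stats::qnorm(prop)
  jack <- vapply(seq_len(n), function(i) safe(seq_len(n)[-i]), numeric(1))
  if (anyNA(jack)) stop("statistic undefined on a jackknife sample")
  d <- mean(jack) - jack
  denom <- 6 * sum(d^2)^1.5
  a <- if (denom > 0) sum(d^3) / denom else 0
  alpha <- (1 - conf) / 2
  adj <- function(z_alpha) {
    stats::pnorm(z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha)))
  }
  qs <- stats::quantile(boot_stat,
                        c(adj(stats::qnorm(alpha)), adj(stats::qnorm(1 - alpha))),
                        type = 6, names = FALSE)
  list(estimate = t0, se = se, ci_low = qs[1], ci_high = qs[2], n = n,
       n_boot = as.integer(n_boot), n_redrawn = n_redrawn, conf = conf,
       seed = seed)
}

#' Correlation with bootstrap SE, BCa interval, and p-value
#'
#' Computes a Pearson or partial correlation between two columns of a data
#' frame, its BCa bootstrap interval (resampling rows, i.e. authors or
#' documents), and the two-tailed p-value from the t transformation of r
#' with `n - 2 - #controls` degrees of freedom. Rows with missing values in
#' any involved column are dropped listwise before resampling.
#'
#' @param data data frame.
#' @param x,y column names.
#' @param controls character vector of control column names (empty for a
#'   plain Pearson correlation).
#' @param n_boot bootstrap replicates (2000 in the study-1 preset, 500 in
#'   study-2; see [ev_config()]).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @return An object of class `correlation_result`: fields `x`, `y`, `r`,
#'   `se`, `ci_low`, `ci_high`, `n`, `n_boot`, `method`, `controls`, `p`,
#'   `seed`.
#' @export
cor_ci <- function(data, x, y, controls = character(0), n_boot = 2000L,
                   seed = 1L, conf = 0.95) {
  stopifnot(is.data.frame(data),
            all(c(x, y, controls) %in% names(data)))
  cols <- data[, c(x, y, controls), drop = FALSE]
  cols <- as.data.frame(lapply(cols, as.numeric))
  cols <- cols[stats::complete.cases(cols), , drop = FALSE]
  k <- length(controls)
  stat <- function(d, idx) {
    di <- d[idx, , drop = FALSE]
    if (k == 0L) pearson_r(di[[1]], di[[2]])
    else partial_correlation(di[[1]], di[[2]], di[, -(1:2), drop = FALSE])
  }
  bs <- bca_bootstrap(stat, cols, n_boot = n_boot, seed = seed, conf = conf)
  r <- bs$estimate
  df <- bs$n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  structure(
    list(x = x, y = y, r = r, se = bs$se, ci_low = bs$ci_low,
         ci_high = bs$ci_high, n = bs$n, n_boot = bs$n_boot,
         method = if (k == 0L) "pearson" else "partial",
         controls = controls, p = 2 * stats::pt(-abs(tval), df),
         n_redrawn = bs$n_redrawn, conf = conf, seed = seed),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  ctrl <- if (length(x$controls)) {
    paste0(" | ", paste(x$controls, collapse = ", "))
  } else ""
  cat(sprintf(
    "%s r(%s, %s%s) = %.3f (SE %.3f), %d%% BCa CI [%.3f, %.3f], n = %d, p = %.3g\n",
    x$method, x$x, x$y, ctrl, x$r, x$se, round(100 * x$conf),
    x$ci_low, x$ci_high, x$n, x$p))
  invisible(x)
}

#' @export
as.data.frame.correlation_result <- function(x, ...) {
  data.frame(x = x$x, y = x$y, method = x$method,
             controls = paste(x$controls, collapse = ","),
             r = x$r, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             n = x$n, n_boot = x$n_boot, p = x$p,
             stringsAsFactors = FALSE)
}

#' Write a correlation report table
#'
#' @param results a `correlation_result` or list of them.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_report <- function(results, path) {
  if (inherits(results, "correlation_result")) results <- list(results)
  tab <- do.call(rbind, lapply(results, as.data.frame))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
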