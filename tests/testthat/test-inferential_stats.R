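test_that("pearson_r handles exact and degenerate inputs", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -3 * x + 2), -1)
  expect_error(pearson_r(x, rep(1, 5)), "constant input")
  expect_error(pearson_r(c(1, 2), c(3, 4)), "at least 3")
  set.seed(401)
  expect_lt(abs(pearson_r(rnorm(10000), rnorm(10000))), 0.05)
})

test_that("partial correlation equals the residual-correlation oracle", {
  set.seed(402)
  for (rep in 1:5) {
    x <- rnorm(50); y <- rnorm(50)
    C <- matrix(rnorm(150), 50, 3)
    expect_equal(partial_correlation(x, y, C),
                 oracle_partial_cor(x, y, C), tolerance = 1e-12)
  }
})

test_that("partial correlation degenerates and errors as specified", {
  set.seed(403)
  x <- rnorm(200); y <- 0.5 * x + rnorm(200)
  # no controls -> exactly pearson
  expect_identical(partial_correlation(x, y), pearson_r(x, y))
  expect_identical(partial_correlation(x, y,
                                       matrix(numeric(0), nrow = 200)),
                   pearson_r(x, y))
  # controls orthogonal to both variables leave r unchanged
  raw <- matrix(rnorm(400), 200, 2)
  Co <- apply(raw, 2, function(cc) lm(cc ~ x + y)$residuals)
  expect_equal(partial_correlation(x, y, Co), pearson_r(x, y),
               tolerance = 1e-10)
  # a fully shared confound is removed
  n <- 5000
  conf <- rnorm(n)
  x2 <- conf + rnorm(n); y2 <- conf + rnorm(n)
  expect_gt(pearson_r(x2, y2), 0.3)
  expect_lt(abs(partial_correlation(x2, y2, cbind(conf))), 0.05)
  # rank deficiency names a collinear column
  C <- cbind(a = x, b = x)
  expect_error(partial_correlation(rnorm(200), rnorm(200), C),
               "rank-deficient controls: b")
  # listwise deletion and the n > k + 2 guard
  expect_error(partial_correlation(c(1, 2, 3, NA), c(1, 2, 3, 4),
                                   cbind(c(1, 0, 1, 0))),
               "complete rows")
})

test_that("estimates are invariant under affine rescaling", {
  set.seed(404)
  x <- rnorm(80); y <- 0.4 * x + rnorm(80); C <- matrix(rnorm(160), 80, 2)
  expect_equal(pearson_r(10 * x - 3, 0.5 * y + 7), pearson_r(x, y))
  expect_equal(partial_correlation(10 * x - 3, 0.5 * y + 7, 2 * C + 1),
               partial_correlation(x, y, C), tolerance = 1e-12)
})

test_that("BCa bootstrap is deterministic and near-percentile for symmetric data", {
  set.seed(405)
  d <- data.frame(v = rnorm(60))
  stat <- function(data, idx) mean(data$v[idx])
  b1 <- bca_bootstrap(stat, d, n_boot = 500, seed = 7)
  b2 <- bca_bootstrap(stat, d, n_boot = 500, seed = 7)
  expect_identical(b1, b2)
  # symmetric statistic: interval close to the plain percentile interval
  set.seed(7)
  boots <- replicate(500, mean(sample(d$v, replace = TRUE)))
  perc <- quantile(boots, c(0.025, 0.975), names = FALSE)
  expect_equal(b1$ci_low, perc[1], tolerance = 0.1)
  expect_equal(b1$ci_high, perc[2], tolerance = 0.1)
  expect_lt(b1$ci_low, b1$estimate)
  expect_gt(b1$ci_high, b1$estimate)
})

test_that("BCa interval agrees with the boot package on the same problem", {
  skip_if_not_installed("boot")
  set.seed(406)
  d <- data.frame(x = rnorm(80))
  d$y <- 0.5 * d$x + rnorm(80)
  stat <- function(data, idx) cor(data$x[idx], data$y[idx])
  ours <- bca_bootstrap(stat, d, n_boot = 4000, seed = 11)
  set.seed(11)
  bt <- boot::boot(d, stat, R = 4000)
  ci <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_equal(ours$ci_low, ci[1], tolerance = 0.03)
  expect_equal(ours$ci_high, ci[2], tolerance = 0.03)
  expect_equal(ours$se, sd(bt$t), tolerance = 0.02)
})

test_that("degenerate resamples are redrawn, then capped at 1%", {
  d <- data.frame(v = c(rep(0, 3), 1:27))
  # undefined on a measurable but small fraction of resamples
  stat <- function(data, idx) {
    x <- data$v[idx]
    if (sd(x) == 0) stop("constant")
    mean(x)
  }
  res <- bca_bootstrap(stat, d, n_boot = 200, seed = 1)
  expect_true(is.finite(res$se))
  # undefined essentially always -> error
  stat_bad <- function(data, idx) NA_real_
  expect_error(bca_bootstrap(stat_bad, d, n_boot = 200, seed = 1),
               "undefined")
})

test_that("cor_ci assembles the full correlation result", {
  set.seed(407)
  n <- 120
  df <- data.frame(a = rnorm(n))
  df$c1 <- rnorm(n)
  df$b <- 0.5 * df$a + 0.3 * df$c1 + rnorm(n)
  res <- cor_ci(df, "a", "b", n_boot = 500, seed = 3)
  expect_s3_class(res, "correlation_result")
  expect_equal(res$method, "pearson")
  expect_equal(res$r, pearson_r(df$a, df$b))
  expect_true(res$ci_low <= res$r && res$r <= res$ci_high)
  expect_lt(res$p, 0.001)
  expect_equal(res$n, n)

  resp <- cor_ci(df, "a", "b", controls = "c1", n_boot = 500, seed = 3)
  expect_equal(resp$method, "partial")
  expect_equal(resp$r, partial_correlation(df$a, df$b, cbind(df$c1)))

  # missing values are dropped listwise before resampling
  df$b[1:5] <- NA
  res2 <- cor_ci(df, "a", "b", n_boot = 500, seed = 3)
  expect_equal(res2$n, n - 5L)

  tab <- as.data.frame(res)
  expect_equal(tab$r, res$r)
  p <- tempfile(fileext = ".tsv")
  write_correlation_report(list(res, resp), p)
  got <- read.delim(p)
  expect_equal(nrow(got), 2L)
  expect_equal(got$method, c("pearson", "partial"))
})
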