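test_that("Welch PSD matches a direct periodogram oracle on a pure tone", {
  # unit sinusoid at 0.05 Hz, TR = 2 s, 145 points
  t <- (0:144) * 2
  x <- sin(2 * pi * 0.05 * t)
  ps <- welch_psd(x, 2)
  peak <- ps$frequencies[which.max(ps$power[1, ])]
  # oracle: direct DFT periodogram of the full series
  xf <- Mod(fft(x - mean(x)))^2
  f_grid <- (0:144) / (145 * 2)
  oracle_peak <- f_grid[which.max(xf[1:73])]
  expect_equal(peak, ps$frequencies[which.min(abs(ps$frequencies - 0.05))])
  expect_lt(abs(peak - oracle_peak), 1 / 64 / 2)  # within one Welch bin
  # zero signal -> zero power; grid capped at Nyquist
  ps0 <- welch_psd(rep(0, 145), 2)
  expect_true(all(ps0$power == 0))
  expect_lte(max(ps$frequencies), 1 / (2 * 2))
  expect_error(welch_psd(rnorm(30), 2), "segment")
})

test_that("Welch PSD integrates to the signal variance (Parseval, white noise)", {
  ratios <- replicate(20, {
    x <- rnorm(145)
    ps <- welch_psd(x, 2)
    df <- ps$frequencies[2] - ps$frequencies[1]
    sum(ps$power[1, ]) * df / var(x)
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("node scores are jointly z-scored and gain-invariant", {
  rec <- toy_recording(n_nodes = 5)
  ps <- welch_psd(rec$data, 2)
  # the concatenated normalized values have mean 0, SD 1 by construction
  keep <- ps$frequencies > 0
  p <- ps$power[, keep]
  z <- (p - mean(p)) / sd(as.vector(p))
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(as.vector(z)) - 1), 1e-9)
  expect_equal(summarize_psd(ps), rowMeans(z))
  # site gain on the raw signal leaves the scores unchanged
  rec_g <- rec
  rec_g$data <- rec$data * 3.7
  expect_equal(summarize_psd(welch_psd(rec_g$data, 2)), summarize_psd(ps),
               tolerance = 1e-12)
  # two-node toy: equal-and-opposite scores symmetric about 0
  toy <- structure(list(frequencies = c(0, 0.1, 0.2),
                        power = rbind(c(1, 2, 2), c(1, 0, 0))),
                   class = "psd_estimate")
  sc <- summarize_psd(toy)
  expect_equal(sc[1], -sc[2])
  # constant PSD -> error
  const <- structure(list(frequencies = c(0, 0.1), power = matrix(1, 2, 2)),
                     class = "psd_estimate")
  expect_error(summarize_psd(const), "zero variance")
})

test_that("one-way ANOVA matches closed-form arithmetic and handles degeneracy", {
  # closed-form oracle: SSB = 1.5, SSW = 4, F = (1.5/1)/(4/4) = 1.5 on (1,4) df
  res <- anova_pvalue(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res$f, 1.5, tolerance = 1e-12)
  expect_equal(res$df, c(1L, 4L))
  expect_equal(res$p, pf(1.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  # zero between-group variance -> F = 0, p = 1
  same <- rep(list(c(1, 2)), 4)
  expect_equal(anova_pvalue(same)$p, 1)
  expect_equal(anova_pvalue(same)$f, 0)
  # all observations identical -> p = 1 by convention
  expect_equal(anova_pvalue(list(c(5, 5), c(5, 5)))$p, 1)
  expect_error(anova_pvalue(list(1:3)), "2 groups")
  expect_error(anova_pvalue(list(1, 1:3)), "2 observations")
})

test_that("ANOVA p-values agree with a permutation-test oracle on small instances", {
  set.seed(31)
  for (i in 1:4) {
    groups <- lapply(1:3, function(g) rnorm(5, mean = 0.4 * (g == 1) * i))
    p_f <- anova_pvalue(groups)$p
    p_perm <- perm_anova_p(groups, n_perm = 4000, seed = 100 + i)
    expect_lt(abs(p_f - p_perm), 0.035)
  }
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(7)
  rej <- mean(replicate(500, {
    anova_pvalue(split(rnorm(24), rep(1:4, each = 6)))$p <= 0.05
  }))
  # binomial 99.9% band around 0.05 at n = 500
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.085)
})

test_that("rank_nodes recovers a planted node and applies the ranking rules", {
  co <- generate_cohort(small_spec())
  rk <- rank_nodes(co)
  expect_equal(rk$top_node, 3)
  expect_true(all(rk$p_values >= 0 & rk$p_values <= 1))
  expect_true(all(diff(rk$p_values[rk$significant_nodes]) >= 0))
  expect_true(all(rk$p_values[rk$significant_nodes] <= rk$alpha))
  # invariance under subject reordering
  perm <- rev(seq_along(co$recordings))
  co_r <- bold_cohort(co$recordings[perm], groups = co$groups)
  rk_r <- rank_nodes(co_r)
  expect_equal(rk_r$p_values, rk$p_values, tolerance = 1e-12)
  expect_identical(rk_r$significant_nodes, rk$significant_nodes)
  # global positive scaling leaves the ranking unchanged
  co_s <- bold_cohort(lapply(co$recordings, function(r) {
    r$data <- r$data * 4.2
    r
  }), groups = co$groups)
  expect_equal(rank_nodes(co_s)$p_values, rk$p_values, tolerance = 1e-9)
  # ranking report mirrors the per-node table structure
  path <- withr::local_tempfile(fileext = ".csv")
  write_ranking_report(rk, path)
  rep <- read.csv(path)
  expect_equal(nrow(rep), length(rk$p_values))
  expect_equal(rep$rank[rk$top_node], 1)
  expect_error(rank_nodes(subset_groups(co, "ASD"), ), "2 groups")
})

test_that("no-significant-node case and p-value ties are handled explicitly", {
  co <- generate_cohort(null_spec(5))
  rk <- rank_nodes(co, alpha = 1e-6)
  expect_length(rk$significant_nodes, 0)
  expect_true(is.na(rk$top_node))
  # tie-break: equal p -> lower node index first (exercised via alpha = 1)
  rk2 <- rank_nodes(co, alpha = 1)
  ties <- duplicated(rk2$p_values[rk2$significant_nodes]) &
    rev(duplicated(rev(rk2$p_values[rk2$significant_nodes])))
  ord <- order(rk2$p_values, seq_along(rk2$p_values))
  expect_identical(rk2$significant_nodes, ord)
})
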