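# One-sample and Welch tests, ANOVA, five-number summaries, reporting.

test_that("one-sample t reproduces printed-summary worked examples", {
  # angle-change test from summary statistics
  r <- one_sample_t(mean = 27.4, sem = 3.5, n = 22, null_value = 0)
  expect_equal(r$t, 27.4 / 3.5, tolerance = 1e-12)
  expect_equal(r$df, 21)
  expect_equal(r$p, 2 * pt(-27.4 / 3.5, 21), tolerance = 1e-12)
  # null-mean input gives p = 1
  expect_equal(one_sample_t(mean = 5, sem = 1, n = 10, null_value = 5)$p, 1)
  expect_equal(one_sample_t(c(-1, 1))$t, 0)
  expect_equal(one_sample_t(c(-1, 1))$p, 1)
  expect_error(one_sample_t(c(2)), "n >= 2")
  expect_error(one_sample_t(mean = 1, sem = 0, n = 5, null_value = 0),
               "degenerate variance")
})

test_that("raw-value and summary routes agree to machine precision", {
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2))
    null <- runif(1, -1, 1)
    a <- one_sample_t(x, null_value = null)
    b <- one_sample_t(mean = mean(x), sem = sd(x) / sqrt(length(x)),
                      n = length(x), null_value = null)
    expect_equal(a$t, b$t, tolerance = 1e-14)
    expect_equal(a$p, b$p, tolerance = 1e-14)
    # independent cross-check against the reference implementation
    ref <- t.test(x, mu = null)
    expect_equal(a$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(a$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("one-sample p agrees with the exact sign-permutation distribution", {
  set.seed(7)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  devs <- vapply(1:50, function(i) {
    x <- rnorm(8)
    r <- one_sample_t(x)
    ts <- apply(signs, 1, function(s) {
      y <- x * s
      mean(y) / (sd(y) / sqrt(8))
    })
    p_perm <- mean(abs(ts) >= abs(r$t) - 1e-12)
    c(r$p, abs(r$p - p_perm))
  }, numeric(2))
  # agreement is tight where it matters (small p) and bounded by the
  # 2^-8 enumeration granularity elsewhere
  expect_lt(median(devs[2, ]), 0.03)
  low <- devs[2, devs[1, ] < 0.2]
  expect_gt(length(low), 5)
  expect_lt(max(low), 0.05)
})

test_that("p-values decrease monotonically in |t| at fixed df", {
  ts <- seq(0, 6, by = 0.25)
  ps <- vapply(ts, function(t0)
    one_sample_t(mean = t0, sem = 1, n = 15)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("Welch pairwise tests match the reference and reduce to pooled df", {
  g <- list(a = rnorm(8, 0, 1), b = rnorm(12, 1, 3), c = rnorm(6, -1, 0.5))
  res <- welch_pairwise(g)
  expect_equal(nrow(res), 3)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    ref <- t.test(g[[pair[1]]], g[[pair[2]]], var.equal = FALSE)
    row <- res[res$group == paste(pair[1], "vs", pair[2]), ]
    expect_equal(row$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(row$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(row$p, ref$p.value, tolerance = 1e-12)
  }
  # identical groups: t = 0, p = 1
  same <- welch_pairwise(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # equal n and equal variance reduce to the pooled df 2n - 2
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(welch_pairwise(list(a = x, b = x + 3))$df, 8,
               tolerance = 1e-12)
  expect_error(welch_pairwise(list(a = 1:3)), "two groups")
})

test_that("one-way ANOVA matches aov and the two-group t identity", {
  set.seed(2)
  g <- list(a = rnorm(7), b = rnorm(9, 0.5), c = rnorm(8, -0.3))
  res <- anova_oneway(g)
  y <- unlist(g)
  fac <- factor(rep(names(g), vapply(g, length, 1L)))
  ref <- summary(aov(y ~ fac))[[1]]
  expect_equal(res$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-10)

  g2 <- list(a = rnorm(10), b = rnorm(10, 1))
  res2 <- anova_oneway(g2)
  tt <- t.test(g2$a, g2$b, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)

  idt <- anova_oneway(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(idt$F, 0)
  expect_equal(idt$p, 1)
})

test_that("five-number summaries follow the interpolated-quartile convention", {
  expect_equal(unname(five_number(1:5)), c(1, 2, 3, 4, 5))
  expect_equal(unname(five_number(7)), rep(7, 5))
  set.seed(4)
  u <- runif(1000)
  fn <- five_number(u)
  expect_true(all(diff(fn) >= 0))
  expect_lt(abs(fn["q1"] - 0.25), 0.05)
  expect_lt(abs(fn["q3"] - 0.75), 0.05)
  expect_error(five_number(numeric(0)), "empty")
})

test_that("the experiment summary assembles tests and ANOVA deterministically", {
  set.seed(9)
  mk_dyn <- function(qs, eps) {
    rbind(
      data.frame(structure_id = paste0("u", seq_along(qs)),
                 role = "unit_AAD", q = qs, dS = NA, eps_A = NA,
                 eps_ER = NA, dD_A = NA, dT_A = NA),
      data.frame(structure_id = paste0("a", seq_along(eps)),
                 role = "alveolus", q = NA,
                 dS = (1 + eps)^2 - 1, eps_A = eps,
                 eps_ER = eps + rnorm(length(eps), 0, 0.01),
                 dD_A = rnorm(length(eps)), dT_A = rnorm(length(eps))))
  }
  dyn <- list(peep0 = mk_dyn(rnorm(6, 0.95, 0.01), rnorm(10, 0.3, 0.05)),
              peep3 = mk_dyn(rnorm(6, 1.02, 0.01), rnorm(10, 0.5, 0.05)))
  rep1 <- summarize_experiment(dyn)
  rep2 <- summarize_experiment(dyn)
  expect_identical(rep1$summary, rep2$summary)
  expect_true(any(grepl("q vs 1", rep1$tests$group)))
  expect_false(is.null(rep1$anova))
  expect_s3_class(rep1, "alveodyn_report")

  single <- summarize_experiment(dyn["peep0"])
  expect_null(single$anova)
  expect_error(summarize_experiment(list(data.frame(x = 1))), "schema")
})
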