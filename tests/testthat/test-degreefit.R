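test_that("degree pmfs are normalized over their support", {
  cases <- list(
    list(fam = "powerlaw", a = 2.5, l = 0, lo = 1, hi = Inf),
    list(fam = "powerlaw", a = 2.0, l = 0, lo = 5, hi = Inf),
    list(fam = "powerlaw", a = 0.8, l = 0, lo = 1, hi = 34),
    list(fam = "exponential", a = 0, l = 0.12, lo = 1, hi = Inf),
    list(fam = "exponential", a = 0, l = 0.5, lo = 1, hi = 34),
    list(fam = "truncated", a = 2, l = 0.05, lo = 5, hi = Inf),
    list(fam = "truncated", a = 0.5, l = 0.01, lo = 1, hi = Inf),
    list(fam = "truncated", a = 1.5, l = 0.3, lo = 1, hi = 20))
  for (cs in cases) {
    hi <- if (is.finite(cs$hi)) cs$hi else cs$lo + 500000
    mass <- sum(degree_pmf(cs$lo:hi, cs$fam, alpha = cs$a, lambda = cs$l,
                           k_min = cs$lo, k_max = cs$hi))
    tol <- if (is.finite(cs$hi)) 1e-9 else 1e-4 # truncation of infinite sums
    expect_lt(abs(mass - 1), tol)
  }
})

test_that("degree_sample validates input and records zeros", {
  s <- degree_sample(c(0, 0, 3, 1, 2))
  expect_equal(s$n_zero, 2)
  expect_equal(sort(s$values), c(1, 2, 3))
  expect_error(degree_sample(c(1.5, 2)), "integers")
  expect_error(degree_sample(c(-1, 2)), "integers")
  expect_error(degree_sample(c(0, 0)), "only zeros")
  expect_error(degree_sample(integer(0)), "empty")
})

test_that("sampler matches the theoretical pmf and is deterministic", {
  # P(1) for alpha = 2.5, k_min = 1 is 1/zeta(2.5) ~ 0.7454
  x <- sample_family("powerlaw", alpha = 2.5, k_min = 1, n = 100000, seed = 1)
  expect_lt(abs(mean(x == 1) - 1 / hurwitz_zeta(2.5, 1)), 0.01)

  # geometric ratio of the exponential pmf
  p <- degree_pmf(1:10, "exponential", lambda = 0.3, k_min = 1)
  expect_equal(p[-1] / p[-10], rep(exp(-0.3), 9), tolerance = 1e-12)

  expect_identical(sample_family("truncated", alpha = 2, lambda = 0.1,
                                 k_min = 1, n = 500, seed = 7),
                   sample_family("truncated", alpha = 2, lambda = 0.1,
                                 k_min = 1, n = 500, seed = 7))
  expect_error(sample_family("powerlaw", alpha = 0.9, k_min = 1, n = 10),
               "alpha > 1")
  expect_error(sample_family("exponential", lambda = -1, k_min = 1, n = 10),
               "lambda")
})

test_that("MLE agrees with a dense grid-search oracle", {
  s <- sample_family("powerlaw", alpha = 2.5, k_min = 5, n = 10000, seed = 2)
  fit <- fit_family(s, "powerlaw", k_min = 5)
  grid <- seq(2.0, 3.0, by = 0.001)
  slk <- sum(log(s)); n <- length(s)
  nll <- vapply(grid, function(a) a * slk + n * log(hurwitz_zeta(a, 5)),
                numeric(1))
  expect_lt(abs(fit$alpha - grid[which.min(nll)]), 0.0011)
  expect_lt(abs(fit$alpha - 2.5), 0.1)

  # exponential MLE has a closed form on the unbounded support
  s2 <- sample_family("exponential", lambda = 0.12, k_min = 1, n = 5000,
                      seed = 3)
  fit2 <- fit_family(s2, "exponential", k_min = 1)
  expect_equal(fit2$lambda, log(1 + 1 / mean(s2 - 1)), tolerance = 1e-6)

  expect_error(fit_family(rep(4L, 50), "powerlaw", k_min = 1), "degenerate")
  expect_error(fit_family(c(5L, 6L), "powerlaw", k_min = 5), "at least 10")
})

test_that("truncated family nests the power law as lambda -> 0", {
  s <- sample_family("powerlaw", alpha = 2.5, k_min = 5, n = 2000, seed = 4)
  ks <- sort(unique(s))
  p_trunc <- degree_pmf(ks, "truncated", alpha = 2.5, lambda = 1e-9,
                        k_min = 5)
  p_pure <- degree_pmf(ks, "powerlaw", alpha = 2.5, k_min = 5)
  expect_lt(max(abs(log(p_trunc) - log(p_pure))), 1e-6)

  # in-sample likelihood nesting: truncated fit is never worse than powerlaw
  fp <- fit_family(s, "powerlaw", k_min = 5)
  ft <- fit_family(s, "truncated", k_min = 5)
  expect_gte(ft$loglik, fp$loglik - 1e-6)
})

test_that("D_KS is zero when empirical and fitted CDFs coincide", {
  # data (1,1,2) x 4 has the exact pmf of the finite power law alpha = 1 on
  # {1, 2}; the MLE recovers alpha = 1 and the KS distance vanishes
  s <- rep(c(1L, 1L, 2L), 4)
  fit <- fit_family(s, "powerlaw", k_min = 1, k_max = 2)
  expect_equal(fit$alpha, 1, tolerance = 1e-5)
  expect_lt(fit$D_KS, 1e-5)
})

test_that("scan_kmin finds the onset of power-law behavior", {
  # pure power law: chosen k_min at or near 1
  ks <- vapply(1:10, function(i)
    scan_kmin(sample_family("powerlaw", alpha = 2.5, k_min = 1, n = 3000,
                            seed = i))$k_min, numeric(1))
  mode_k <- as.integer(names(which.max(table(ks))))
  expect_lte(mode_k, 3)

  # exponential below 10, power law above: chosen k_min near 10
  ks2 <- vapply(1:10, function(i) {
    set.seed(100 + i)
    head_v <- sample_family("exponential", lambda = 0.35, k_min = 1,
                            n = 3750, k_max = 9)
    tail_v <- sample_family("powerlaw", alpha = 2.5, k_min = 10, n = 1250)
    scan_kmin(c(head_v, tail_v))$k_min
  }, numeric(1))
  expect_lte(abs(stats::median(ks2) - 10), 3)

  # the kmin_max cap is respected even while D_KS is still decreasing
  set.seed(5)
  mix <- c(sample_family("exponential", lambda = 0.25, k_min = 1, n = 4000,
                         k_max = 19),
           sample_family("powerlaw", alpha = 2.5, k_min = 20, n = 1000))
  expect_lte(scan_kmin(mix, kmin_max = 5)$k_min, 5)
  expect_error(scan_kmin(c(rep(1L, 5), 2L), kmin_max = 50), "tail points")
})

test_that("gof_bootstrap accepts its own model and rejects a wrong one", {
  smp <- sample_family("powerlaw", alpha = 2.5, k_min = 1, n = 300, seed = 6)
  sc <- scan_kmin(smp, kmin_max = 10)
  p_null <- suppressWarnings(
    gof_bootstrap(smp, sc, n_sets = 80, seed = 7, kmin_max = 10))
  expect_gte(p_null, 0)
  expect_lte(p_null, 1)
  expect_gt(p_null, 0.1) # own-model data should look plausible

  # grossly exponential data against a power-law fit
  smp2 <- sample_family("exponential", lambda = 0.3, k_min = 1, n = 800,
                        seed = 8)
  sc2 <- scan_kmin(smp2, kmin_max = 10)
  p_bad <- suppressWarnings(
    gof_bootstrap(smp2, sc2, n_sets = 80, seed = 9, kmin_max = 10))
  expect_lt(p_bad, 0.1)

  expect_warning(gof_bootstrap(smp, sc, n_sets = 50, seed = 1,
                               kmin_max = 10), "resolution")
})

test_that("cv_select recovers generating families", {
  # large geometric sample -> exponential
  fams <- vapply(1:5, function(i)
    cv_select(sample_family("exponential", lambda = 0.25, k_min = 1,
                            n = 8000, seed = 20 + i),
              k_min = 1, seed = i)$family, character(1))
  expect_gte(sum(fams == "exponential"), 4)

  # pure power law -> powerlaw or truncated, never exponential
  fams2 <- vapply(1:5, function(i)
    cv_select(sample_family("powerlaw", alpha = 2.5, k_min = 5, n = 8000,
                            seed = 30 + i),
              k_min = 5, seed = i)$family, character(1))
  expect_true(all(fams2 %in% c("powerlaw", "truncated")))

  # truncated sample: truncated beats pure powerlaw in held-out likelihood
  wins <- vapply(1:5, function(i) {
    cv <- cv_select(sample_family("truncated", alpha = 2, lambda = 0.05,
                                  k_min = 5, n = 8000, seed = 40 + i),
                    k_min = 5, seed = i)$cv_loglik
    cv[["truncated"]] > cv[["powerlaw"]]
  }, logical(1))
  expect_gte(sum(wins), 4)
})

test_that("fit_below_kmin fits the head on its finite support", {
  set.seed(50)
  head_v <- sample_family("exponential", lambda = 0.12, k_min = 1, n = 5000,
                          k_max = 34)
  tail_v <- sample_family("powerlaw", alpha = 2.9, k_min = 35, n = 300)
  res <- fit_below_kmin(c(head_v, tail_v), k_min = 35, seed = 51)
  expect_equal(res$family, "exponential")
  expect_gte(res$fits$exponential$lambda, 0.10)
  expect_lte(res$fits$exponential$lambda, 0.14)

  # fitted mass sums to 1 over [1, k_min - 1]
  f <- res$fits$exponential
  mass <- sum(degree_pmf(1:34, "exponential", lambda = f$lambda,
                         k_min = 1, k_max = 34))
  expect_lt(abs(mass - 1), 1e-9)

  # a power-law-shaped head prefers the power law
  set.seed(52)
  head_p <- sample_family("powerlaw", alpha = 2.2, k_min = 1, n = 5000,
                          k_max = 34)
  res2 <- fit_below_kmin(c(head_p, tail_v), k_min = 35, seed = 53)
  cv <- res2$cv_loglik
  expect_equal(names(which.max(cv)), "powerlaw")

  expect_error(fit_below_kmin(rep(40L, 20), k_min = 35), "below k_min")
})

test_that("powerlaw_code renders the gof and CV summary", {
  expect_equal(powerlaw_code(0.5, c(powerlaw = -176.41, truncated = -175.60,
                                    exponential = -176.63)), "+T")
  expect_equal(powerlaw_code(0.01, c(powerlaw = -175.62, truncated = -175.60,
                                     exponential = -176.63)), "-PT")
  expect_equal(powerlaw_code(0.2, c(powerlaw = -10.02, truncated = -10.04,
                                    exponential = -10.01)), "+PTE")
})
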