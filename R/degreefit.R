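#' Degree-distribution fitting for semantic networks
#'
#' Discrete maximum-likelihood fitting of in-degree (or any positive integer)
#' samples under three families: the power law P(k) ~ k^-alpha, the truncated
#' power law P(k) ~ k^-alpha exp(-lambda k) and the exponential
#' P(k) ~ exp(-lambda k), all normalized over an integer support
#' [k_min, k_max]. The lower bound k_min is selected by minimizing the
#' Kolmogorov-Smirnov distance, goodness of fit is assessed by a
#' semi-parametric bootstrap, and families are compared by k-fold
#' cross-validated held-out log-likelihood.
#'
#' @name degreefit
NULL

FAMILIES <- c("powerlaw", "truncated", "exponential")

#' Hurwitz zeta function
#'
#' Computes \eqn{\zeta(s, q) = \sum_{j \ge 0} (q + j)^{-s}} for `s > 1` by
#' Euler-Maclaurin summation. Used as the normalizing constant of the discrete
#' power law on an unbounded support. Vectorized over `q`.
#'
#' @param s exponent, a single number greater than 1
#' @param q offset(s), positive
#' @return numeric vector the length of `q`
#' @export
hurwitz_zeta <- function(s, q, terms = 30L) {
  stopifnot(length(s) == 1L, s > 1, all(q > 0))
  qn <- q + terms
  direct <- rowSums(outer(q, seq_len(terms) - 1, `+`)^(-s))
  direct + qn^(1 - s) / (s - 1) + 0.5 * qn^(-s) +
    s / 12 * qn^(-s - 1) -
    s * (s + 1) * (s + 2) / 720 * qn^(-s - 3) +
    s * (s + 1) * (s + 2) * (s + 3) * (s + 4) / 30240 * qn^(-s - 5)
}

# log normalizing constant of a family over integer support [lower, upper]
log_norm_const <- function(family, alpha, lambda, lower, upper = Inf) {
  if (is.finite(upper)) {
    ks <- lower:upper
    lt <- switch(family,
      powerlaw = -alpha * log(ks),
      exponential = -lambda * ks,
      truncated = -alpha * log(ks) - lambda * ks)
    mx <- max(lt)
    return(mx + log(sum(exp(lt - mx))))
  }
  switch(family,
    powerlaw = {
      if (alpha <= 1) return(Inf)
      log(hurwitz_zeta(alpha, lower))
    },
    exponential = {
      if (lambda <= 0) return(Inf)
      -lambda * lower - log1p(-exp(-lambda))
    },
    truncated = {
      if (lambda <= 0) {
        if (alpha <= 1) return(Inf)
        return(log(hurwitz_zeta(alpha, lower)))
      }
      # direct sum over a head whose length scales with 1/lambda, then a
      # midpoint-rule integral for the remaining tail
      kcap <- lower + min(49999, max(64, ceiling(30 / max(lambda, 6e-4))))
      ks <- lower:kcap
      lt <- -alpha * log(ks) - lambda * ks
      mx <- max(lt)
      s <- sum(exp(lt - mx))
      tail <- 0
      if (exp(lt[length(lt)] - mx) > 1e-16 * s) {
        f <- function(x) exp(-alpha * log(x) - lambda * x - mx)
        tail <- tryCatch(
          integrate(f, kcap + 0.5, Inf, rel.tol = 1e-10)$value,
          error = function(e) 0)
      }
      mx + log(s + tail)
    })
}

#' Probability mass function of the fitted degree families
#'
#' @param k positive integer values at which to evaluate
#' @param family one of `"powerlaw"`, `"truncated"`, `"exponential"`
#' @param alpha power-law exponent (ignored for `"exponential"`)
#' @param lambda exponential rate (ignored for `"powerlaw"`)
#' @param k_min,k_max integer support bounds (`k_max` may be `Inf`)
#' @return vector of probabilities; zero outside the support
#' @export
degree_pmf <- function(k, family = FAMILIES, alpha = NULL, lambda = NULL,
                       k_min = 1L, k_max = Inf) {
  family <- match.arg(family)
  lz <- log_norm_const(family, alpha, lambda, k_min, k_max)
  lp <- switch(family,
    powerlaw = -alpha * log(k),
    exponential = -lambda * k,
    truncated = -alpha * log(k) - lambda * k)
  out <- exp(lp - lz)
  out[k < k_min | k > k_max | k != floor(k)] <- 0
  out
}

#' Construct a degree sample
#'
#' Validates a vector of node degrees for distribution fitting. Zeros are
#' excluded (logarithmic fitting requires k >= 1); their count is kept in the
#' `n_zero` field.
#'
#' @param values integer degrees, non-negative
#' @param source optional character descriptor of where the degrees came from
#' @return an object of class `degree_sample` with fields `values`, `n_zero`
#'   and `source`
#' @export
degree_sample <- function(values, source = "") {
  if (length(values) == 0) stopf("empty degree sample")
  if (any(!is.finite(values)) || any(values < 0) || any(values != floor(values)))
    stopf("degrees must be non-negative integers")
  n_zero <- sum(values == 0)
  values <- as.integer(values[values > 0])
  if (length(values) == 0) stopf("degree sample contains only zeros")
  structure(list(values = values, n_zero = n_zero, source = source),
            class = "degree_sample")
}

#' In-degree sample of a directed network
#'
#' @param net a directed `igraph` network
#' @return a [degree_sample()] of the positive in-degrees
#' @export
in_degree_sample <- function(net) {
  stopifnot(igraph::is_directed(net))
  degree_sample(igraph::degree(net, mode = "in"), source = "in-degree")
}

as_degree_values <- function(sample) {
  if (inherits(sample, "degree_sample")) sample$values
  else degree_sample(sample)$values
}

# sup_k | ecdf(k) - F(k) | over all integers in the support covered by data
ks_distance <- function(tail_values, family, alpha, lambda, k_min, k_max = Inf) {
  hi <- max(tail_values)
  ks <- k_min:hi
  pmf <- degree_pmf(ks, family, alpha = alpha, lambda = lambda,
                    k_min = k_min, k_max = k_max)
  fit_cdf <- cumsum(pmf)
  emp_cdf <- cumsum(tabulate(tail_values - k_min + 1L, nbins = length(ks))) /
    length(tail_values)
  max(abs(emp_cdf - fit_cdf))
}

#' Fit one degree-distribution family by discrete maximum likelihood
#'
#' The log-likelihood depends on the data only through `n`, `sum(log k)` and
#' `sum(k)` over the tail `k_min <= k <= k_max`, so fitting cost is independent
#' of sample size. Power-law and exponential fits use one-dimensional
#' minimization; the truncated power law uses box-constrained quasi-Newton from
#' two starting points. The Kolmogorov-Smirnov distance between the empirical
#' and fitted CDFs on the tail is returned alongside.
#'
#' @param sample a [degree_sample()] or a vector of positive integers
#' @param family one of `"powerlaw"`, `"truncated"`, `"exponential"`
#' @param k_min lower support bound of the fit
#' @param k_max upper support bound (default unbounded); finite values are used
#'   when fitting the head of a distribution below some k_min
#' @return an object of class `degree_fit`: a list with `family`, `alpha`,
#'   `lambda`, `k_min`, `k_max`, `n_tail`, `loglik` and `D_KS`
#' @export
fit_family <- function(sample, family = FAMILIES, k_min = 1L, k_max = Inf) {
  family <- match.arg(family)
  values <- as_degree_values(sample)
  tail_values <- values[values >= k_min & values <= k_max]
  n <- length(tail_values)
  if (n < 10) stopf("need at least 10 observations in [%s, %s]; got %d",
                    k_min, k_max, n)
  if (length(unique(tail_values)) < 2)
    stopf("degenerate sample (all values equal): MLE diverges")
  slk <- sum(log(tail_values))
  sk <- sum(tail_values)
  a_lo <- if (is.finite(k_max)) 1e-3 else 1 + 1e-6

  nll <- function(alpha = 0, lambda = 0)
    switch(family,
      powerlaw = alpha * slk +
        n * log_norm_const("powerlaw", alpha, 0, k_min, k_max),
      exponential = lambda * sk +
        n * log_norm_const("exponential", 0, lambda, k_min, k_max),
      truncated = alpha * slk + lambda * sk +
        n * log_norm_const("truncated", alpha, lambda, k_min, k_max))

  if (family == "powerlaw") {
    opt <- optimize(function(a) nll(alpha = a), c(a_lo, 25), tol = 1e-9)
    alpha <- opt$minimum; lambda <- 0; value <- opt$objective
  } else if (family == "exponential") {
    opt <- optimize(function(l) nll(lambda = l), c(1e-9, 20), tol = 1e-9)
    alpha <- 0; lambda <- opt$minimum; value <- opt$objective
  } else {
    obj <- function(par) nll(alpha = par[1], lambda = par[2])
    best <- NULL
    for (start in list(c(1.5, 0.05), c(2.5, 1e-3))) {
      opt <- tryCatch(
        optim(start, obj, method = "L-BFGS-B",
              lower = c(1e-3, 1e-9), upper = c(25, 20),
              control = list(factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value))
        best <- opt
    }
    if (is.null(best)) stopf("truncated power-law fit failed")
    alpha <- best$par[1]; lambda <- best$par[2]; value <- best$value
  }

  structure(list(
    family = family, alpha = alpha, lambda = lambda,
    k_min = k_min, k_max = k_max, n_tail = n, loglik = -value,
    D_KS = ks_distance(tail_values, family, alpha, lambda, k_min, k_max)),
    class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("degree_fit: %s on [%s, %s], n_tail = %d\n",
              x$family, x$k_min, x$k_max, x$n_tail))
  cat(sprintf("  alpha = %.4f  lambda = %.6f  logLik = %.2f  D_KS = %.4f\n",
              x$alpha, x$lambda, x$loglik, x$D_KS))
  invisible(x)
}

#' Select the power-law lower bound k_min by KS-distance minimization
#'
#' Fits the discrete power law at every candidate `k_min` in `1:kmin_max` that
#' leaves at least 10 tail observations and returns the candidate minimizing
#' the Kolmogorov-Smirnov distance (ties broken toward the smallest `k_min`).
#'
#' @param sample a [degree_sample()] or vector of positive integers
#' @param kmin_max largest candidate lower bound (default 50)
#' @return list with `k_min`, the winning power-law `fit`, and a `scan`
#'   data frame (one row per candidate)
#' @export
scan_kmin <- function(sample, kmin_max = 50L) {
  stopifnot(kmin_max >= 1)
  values <- as_degree_values(sample)
  cand <- Filter(function(k) sum(values >= k) >= 10, seq_len(kmin_max))
  if (length(cand) == 0)
    stopf("no candidate k_min <= %d leaves at least 10 tail points", kmin_max)
  fits <- lapply(cand, function(k)
    tryCatch(fit_family(values, "powerlaw", k_min = k), error = function(e) NULL))
  keep <- !vapply(fits, is.null, logical(1))
  cand <- cand[keep]; fits <- fits[keep]
  if (length(cand) == 0) stopf("power-law fit failed at every candidate k_min")
  dks <- vapply(fits, `[[`, numeric(1), "D_KS")
  i <- which.min(dks)
  list(k_min = cand[i], fit = fits[[i]],
       scan = data.frame(
         k_min = cand,
         alpha = vapply(fits, `[[`, numeric(1), "alpha"),
         D_KS = dks,
         n_tail = vapply(fits, `[[`, numeric(1), "n_tail")))
}

#' Semi-parametric bootstrap goodness-of-fit test for the power law
#'
#' Each synthetic data set matches the observed sample size: with probability
#' equal to the empirical tail fraction a value is drawn from the fitted
#' power-law tail, otherwise it is resampled from the observed values below
#' `k_min`. Each synthetic set is re-fitted with its own k_min scan, and the
#' returned p-value is the fraction of synthetic sets whose KS distance
#' exceeds the observed one. The power law is considered plausible when
#' `p > 0.1`.
#'
#' @param sample the observed [degree_sample()]
#' @param fit result of [scan_kmin()] (the list, or its `fit` element with a
#'   matching `k_min`)
#' @param n_sets number of bootstrap sets (default 1000; fewer than 100 gives
#'   a warning about p-value resolution)
#' @param seed optional RNG seed
#' @param kmin_max candidate range for the per-set k_min scan
#' @return the goodness-of-fit probability `gof_p` in `[0, 1]`
#' @export
gof_bootstrap <- function(sample, fit, n_sets = 1000L, seed = NULL,
                          kmin_max = 50L) {
  if (is.list(fit) && !inherits(fit, "degree_fit") && !is.null(fit$fit))
    fit <- fit$fit
  stopifnot(inherits(fit, "degree_fit"), fit$family == "powerlaw")
  if (n_sets < 100) warnf("n_sets < 100: gof_p resolution is coarse")
  values <- as_degree_values(sample)
  n <- length(values)
  head_values <- values[values < fit$k_min]
  p_tail <- 1 - length(head_values) / n
  d_obs <- fit$D_KS
  with_seed(seed, {
    d_syn <- vapply(seq_len(n_sets), function(i) {
      n_tail <- rbinom(1, n, p_tail)
      syn <- c(
        if (n - n_tail > 0) sample(head_values, n - n_tail, replace = TRUE),
        if (n_tail > 0) sample_family("powerlaw", alpha = fit$alpha,
                                      k_min = fit$k_min, n = n_tail))
      tryCatch(scan_kmin(syn, kmin_max = kmin_max)$fit$D_KS,
               error = function(e) NA_real_)
    }, numeric(1))
    mean(d_syn > d_obs, na.rm = TRUE)
  })
}

#' Model selection among degree families by k-fold cross-validation
#'
#' Tail observations (`k >= k_min`) are assigned to folds at random; each
#' family is fitted on the training portion and scored by the summed held-out
#' log-likelihood, averaged over folds. The family with the greatest mean
#' held-out log-likelihood wins. All three means are reported so that ties at
#' one decimal place can be displayed jointly (see [powerlaw_code()]).
#'
#' @param sample a [degree_sample()] or vector of positive integers
#' @param k_min common lower bound for all families
#' @param folds number of folds (default 10)
#' @param seed optional RNG seed for the fold assignment
#' @param k_max upper support bound (finite when fitting a distribution head)
#' @return list with `family` (the winner), `cv_loglik` (named mean held-out
#'   log-likelihoods) and `folds` (per-fold matrix)
#' @export
cv_select <- function(sample, k_min = 1L, folds = 10L, seed = NULL,
                      k_max = Inf) {
  stopifnot(folds >= 2)
  values <- as_degree_values(sample)
  tail_values <- values[values >= k_min & values <= k_max]
  if (length(tail_values) < folds)
    stopf("need at least %d observations >= k_min", folds)
  with_seed(seed, {
    fold_id <- sample(rep(seq_len(folds), length.out = length(tail_values)))
    ll <- matrix(NA_real_, folds, length(FAMILIES),
                 dimnames = list(NULL, FAMILIES))
    for (f in seq_len(folds)) {
      train <- tail_values[fold_id != f]
      test <- tail_values[fold_id == f]
      if (length(test) == 0) next
      for (fam in FAMILIES) {
        fit <- tryCatch(fit_family(train, fam, k_min = k_min, k_max = k_max),
                        error = function(e) NULL)
        if (is.null(fit)) {
          warnf("%s fit failed in fold %d; fold skipped for that family",
                fam, f)
          next
        }
        ll[f, fam] <- sum(log(degree_pmf(test, fam, alpha = fit$alpha,
                                         lambda = fit$lambda,
                                         k_min = k_min, k_max = k_max)))
      }
    }
    cv <- colMeans(ll, na.rm = TRUE)
    if (all(!is.finite(cv))) stopf("all folds failed for every family")
    list(family = names(cv)[which.max(cv)], cv_loglik = cv, folds = ll)
  })
}

#' Fit the head of a degree distribution below k_min
#'
#' Fits all three families restricted to the finite support
#' `[1, k_min - 1]` (discrete normalization over that range) and selects among
#' them by cross-validated held-out log-likelihood.
#'
#' @inheritParams cv_select
#' @return list with `family` (the selected one), `fits` (each family fitted
#'   to the full head data) and `cv_loglik`
#' @export
fit_below_kmin <- function(sample, k_min, folds = 10L, seed = NULL) {
  stopifnot(k_min >= 3)
  values <- as_degree_values(sample)
  head_values <- values[values < k_min]
  if (length(head_values) < 10)
    stopf("need at least 10 observations below k_min")
  sel <- cv_select(head_values, k_min = 1L, folds = folds, seed = seed,
                   k_max = k_min - 1L)
  fits <- lapply(FAMILIES, function(fam)
    fit_family(head_values, fam, k_min = 1L, k_max = k_min - 1L))
  names(fits) <- FAMILIES
  list(family = sel$family, fits = fits, cv_loglik = sel$cv_loglik)
}

#' Draw an exact sample from a fitted degree family
#'
#' Inverse-CDF sampling on the normalized probability mass function; the
#' support table is extended adaptively until it covers every uniform draw.
#'
#' @param family one of `"powerlaw"`, `"truncated"`, `"exponential"`
#' @param alpha,lambda family parameters (power law on an unbounded support
#'   requires `alpha > 1`; exponential and truncated require `lambda > 0`)
#' @param k_min,k_max integer support bounds
#' @param n number of draws
#' @param seed optional RNG seed
#' @return integer vector of degrees
#' @export
sample_family <- function(family = FAMILIES, alpha = NULL, lambda = NULL,
                          k_min = 1L, n, seed = NULL, k_max = Inf) {
  family <- match.arg(family)
  if (family != "exponential" && (is.null(alpha) || alpha <= 0))
    stopf("alpha must be positive")
  if (family != "powerlaw" && (is.null(lambda) || lambda <= 0))
    stopf("lambda must be positive")
  if (family == "powerlaw" && !is.finite(k_max) && alpha <= 1)
    stopf("power law on unbounded support requires alpha > 1")
  if (is.null(alpha)) alpha <- 0
  if (is.null(lambda)) lambda <- 0
  lz <- log_norm_const(family, alpha, lambda, k_min, k_max)
  lpmf <- function(k) switch(family,
    powerlaw = -alpha * log(k) - lz,
    exponential = -lambda * k - lz,
    truncated = -alpha * log(k) - lambda * k - lz)
  with_seed(seed, {
    u <- runif(n)
    hi <- min(k_max, k_min + 1023)
    cdf <- cumsum(exp(lpmf(k_min:hi)))
    while (cdf[length(cdf)] < max(u) && hi < k_max) {
      lo2 <- hi + 1
      hi <- min(k_max, k_min + 2 * (hi - k_min) + 1)
      cdf <- c(cdf, cdf[length(cdf)] + cumsum(exp(lpmf(lo2:hi))))
      if (hi - k_min > 1e8) stopf("sampling table exceeded 1e8 entries")
    }
    as.integer(k_min + findInterval(u, cdf))
  })
}

#' Summary code for power-law testing of a degree distribution
#'
#' Builds the compact code used to summarize degree-distribution tests: a
#' leading `+` if the bootstrap goodness-of-fit probability exceeds 0.1 (the
#' power law is plausible) or `-` otherwise, followed by the letters of every
#' family whose mean cross-validated log-likelihood, rounded to one decimal
#' place, equals the best one (`P` = power law, `T` = truncated power law,
#' `E` = exponential, always in that order).
#'
#' @param gof_p goodness-of-fit probability from [gof_bootstrap()]
#' @param cv_loglik named mean held-out log-likelihoods from [cv_select()]
#' @return a character code such as `"+PT"` or `"-T"`
#' @export
powerlaw_code <- function(gof_p, cv_loglik) {
  stopifnot(all(FAMILIES %in% names(cv_loglik)))
  r <- round(cv_loglik[FAMILIES], 1)
  sym <- c(powerlaw = "P", truncated = "T", exponential = "E")
  paste0(if (gof_p > 0.1) "+" else "-",
         paste(sym[FAMILIES][r == max(r, na.rm = TRUE)], collapse = ""))
}
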