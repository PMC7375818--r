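#' Significance threshold by sampling basis
#'
#' Dual-threshold convention for synapse studies: p < 0.05 when the sample
#' size is the number of subjects (ANOVA, Mann-Whitney on per-subject means),
#' p < 0.001 when the sample size is the number of synapses (KS, chi-squared),
#' to avoid overstating differences driven by very large n.
#'
#' @param n_basis \code{"subjects"} or \code{"synapses"}.
#' @return the alpha to use.
#' @export
significance_alpha <- function(n_basis = c("subjects", "synapses")) {
  switch(match.arg(n_basis), subjects = 0.05, synapses = 0.001)
}

make_test_result <- function(method, statistic, df = NA_real_, p, n_basis,
                             alpha = significance_alpha(n_basis),
                             extra = NULL) {
  structure(c(list(method = method, statistic = unname(statistic),
                   df = unname(df), p = unname(p), alpha = alpha,
                   n_basis = n_basis, significant = unname(p) < alpha),
              extra),
            class = "synstat_test")
}

#' @export
print.synstat_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f%s, p = %.4g (alpha = %g, n basis: %s) %s\n",
              x$method, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %g", x$df),
              x$p, x$alpha, x$n_basis,
              if (x$significant) "*" else ""))
  invisible(x)
}

#' Chi-squared test of association for a contingency table
#'
#' Expected frequencies are computed from the marginal totals as
#' E_ij = T_i * T_j / T; the statistic is sum((O - E)^2 / E) with
#' (rows - 1)(cols - 1) degrees of freedom and no continuity correction.
#' The synapse-level alpha (0.001) applies by default.
#'
#' @param tab matrix of nonnegative counts.
#' @param n_basis sampling basis for the significance threshold.
#' @return a \code{synstat_test} with an \code{expected} matrix attached.
#' @examples
#' chi2_contingency(rbind(c(10, 20), c(20, 10)))  # statistic 6.667, df 1
#' @export
chi2_contingency <- function(tab, n_basis = "synapses") {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("'tab' must contain nonnegative integer counts", call. = FALSE)
  T_ <- sum(tab)
  if (T_ == 0) stop("all-zero contingency table", call. = FALSE)
  Ti <- rowSums(tab); Tj <- colSums(tab)
  expected <- outer(Ti, Tj) / T_
  if (any(expected < 5))
    warning("some expected frequencies are below 5; chi-squared approximation may be poor")
  nonzero <- expected > 0
  stat <- sum((tab[nonzero] - expected[nonzero])^2 / expected[nonzero])
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p <- pchisq(stat, df, lower.tail = FALSE)
  make_test_result("chi-squared", stat, df, p, n_basis,
                   extra = list(expected = expected))
}

#' Pairwise post-hoc chi-squared comparisons between groups
#'
#' For a 2 x K table (e.g. AS/SS counts per layer), tests every pair of
#' columns as a 2 x 2 sub-table at the synapse-level alpha. No additional
#' multiple-testing correction is applied beyond the strict alpha.
#'
#' @param tab a 2 x K count matrix with column names.
#' @param n_basis sampling basis (default synapses).
#' @return data.frame with one row per pair: statistic, df, p, significant.
#' @export
chi2_posthoc_pairwise <- function(tab, n_basis = "synapses") {
  tab <- as.matrix(tab)
  K <- ncol(tab)
  cols <- colnames(tab) %||% paste0("g", seq_len(K))
  pairs <- utils::combn(K, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tr <- suppressWarnings(chi2_contingency(tab[, c(i, j)], n_basis))
    data.frame(group1 = cols[i], group2 = cols[j],
               statistic = tr$statistic, df = tr$df, p = tr$p,
               significant = tr$significant, stringsAsFactors = FALSE)
  }))
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two empirical distributions (e.g. SAS-area distributions of AS
#' and SS); the statistic is the supremum difference of the empirical CDFs.
#' Synapse-level alpha (0.001) by default.
#'
#' @param x,y numeric samples.
#' @param n_basis sampling basis.
#' @return a \code{synstat_test}.
#' @export
ks_two_sample <- function(x, y, n_basis = "synapses") {
  if (!length(x) || !length(y)) stop("empty input sample", call. = FALSE)
  kt <- suppressWarnings(ks.test(x, y))
  make_test_result("Kolmogorov-Smirnov", kt$statistic, NA_real_, kt$p.value,
                   n_basis)
}

#' Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' Two-sided rank test; the exact permutation distribution is used for small
#' untied samples and the normal approximation with tie correction otherwise.
#' Subject-level alpha (0.05) by default.
#'
#' @param x,y numeric samples.
#' @param n_basis sampling basis.
#' @param exact force (or forbid) the exact distribution; default as
#'   \code{wilcox.test}: exact iff both samples are small and untied.
#' @return a \code{synstat_test}.
#' @export
mann_whitney <- function(x, y, n_basis = "subjects", exact = NULL) {
  if (!length(x) || !length(y)) stop("empty input sample", call. = FALSE)
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = FALSE))
  make_test_result("Mann-Whitney", wt$statistic, NA_real_, wt$p.value,
                   n_basis)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Classical (equal-variance) one-way analysis of variance across groups,
#' followed by Tukey honestly-significant-difference pairwise comparisons.
#' Subject-level alpha (0.05) by default.
#'
#' @param groups named list of numeric vectors (each of length >= 2).
#' @param n_basis sampling basis.
#' @return a \code{synstat_test} with a \code{pairwise} data.frame attached
#'   (columns comparison, diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(groups, n_basis = "subjects") {
  if (!length(groups) || any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  fit <- aov(value ~ group, data = df)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"], row.names = NULL,
                         stringsAsFactors = FALSE)
  make_test_result("one-way ANOVA", sm$`F value`[1], sm$Df[1],
                   sm$`Pr(>F)`[1], n_basis, extra = list(pairwise = pairwise))
}

# KS distance between a sample and a fitted CDF (sup over both one-sided gaps)
ks_distance_fitted <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n)
}

# log-logistic with CDF(x) = 1 / (1 + (x / scale)^(-shape))
dllogis <- function(x, scale, shape) {
  z <- (x / scale)^shape
  (shape / x) * z / (1 + z)^2
}
pllogis <- function(q, scale, shape) 1 / (1 + (q / scale)^(-shape))

#' Fit a right-skewed size distribution (log-normal or log-logistic)
#'
#' Synaptic apposition surface areas follow right-skewed distributions well
#' described by log-normal or log-logistic families. The log-normal fit uses
#' the closed-form MLE on log values; the log-logistic (CDF
#' 1/(1 + (x/scale)^(-shape))) is fitted by numerical maximum likelihood.
#' The KS distance against the fitted CDF and the AIC allow model comparison.
#'
#' @param x strictly positive sample, n >= 10, not all equal.
#' @param family \code{"lognormal"} or \code{"loglogistic"}.
#' @return object of class \code{size_fit}: family, parameters, log
#'   likelihood, AIC and KS distance.
#' @export
fit_size_distribution <- function(x, family = c("lognormal", "loglogistic")) {
  family <- match.arg(family)
  if (any(x <= 0)) stop("sample must be strictly positive", call. = FALSE)
  if (length(x) < 10) stop("need at least 10 observations", call. = FALSE)
  if (var(x) == 0) stop("constant sample: nothing to fit", call. = FALSE)
  lx <- log(x)
  n <- length(x)
  if (family == "lognormal") {
    mu <- mean(lx)
    sigma <- sqrt(mean((lx - mu)^2))  # MLE (divisor n)
    ll <- sum(stats::dlnorm(x, mu, sigma, log = TRUE))
    params <- c(meanlog = mu, sdlog = sigma)
    ks <- ks_distance_fitted(x, function(q) plnorm(q, mu, sigma))
  } else {
    # moment-based start: log-logistic logs are logistic(log scale, 1/shape)
    start <- c(log_scale = median(lx), log_shape = log(pi / (sqrt(3) * sd(lx))))
    nll <- function(par) {
      sc <- exp(par[1]); sh <- exp(par[2])
      -sum(log(dllogis(x, sc, sh)))
    }
    opt <- optim(start, nll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    sc <- exp(opt$par[1]); sh <- exp(opt$par[2])
    ll <- -opt$value
    params <- c(scale = unname(sc), shape = unname(sh))
    ks <- ks_distance_fitted(x, function(q) pllogis(q, sc, sh))
  }
  structure(list(family = family, params = params, loglik = ll,
                 aic = 2 * 2 - 2 * ll, ks = ks, n = n),
            class = "size_fit")
}

#' @export
print.size_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): %s; logLik = %.2f, AIC = %.2f, KS = %.4f\n",
              x$family, x$n,
              paste(sprintf("%s = %.4f", names(x$params), x$params),
                    collapse = ", "),
              x$loglik, x$aic, x$ks))
  invisible(x)
}

#' Coefficient of determination (squared Pearson correlation)
#'
#' R^2 between two variables; sign-free, so a strong negative (indirect)
#' association also yields a value near 1.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return R^2 in [0, 1].
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  cor(x, y)^2
}
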