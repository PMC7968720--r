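#' Pearson model fit
#'
#' Correlation-based fit of a prediction vector to observed proportions:
#' Pearson's r, the adjusted coefficient of determination of the
#' one-predictor regression of observed on predicted
#' (\eqn{R^2_{adj} = 1 - (1 - r^2)(n-1)/(n-2)}), and the t statistic
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} with its two-sided p value on n-2
#' degrees of freedom.
#'
#' @param predicted,observed Numeric vectors of equal length (n >= 3), each
#'   with non-zero variance.
#' @return An object of class `model_fit`: list with `r`, `r2_adj`, `t`,
#'   `df`, `p`, `n`.
#' @examples
#' pearson_fit(c(.1, .5, .9, .3), c(.2, .4, .8, .35))
#' @export
pearson_fit <- function(predicted, observed) {
  n <- length(predicted)
  if (length(observed) != n) stop("vectors differ in length", call. = FALSE)
  if (n < 3L) stop("need at least 3 paired cells", call. = FALSE)
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  r <- stats::cor(predicted, observed)
  df <- n - 2L
  r2_adj <- 1 - (1 - r^2) * (n - 1) / df
  t <- r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(r = r, r2_adj = r2_adj, t = t, df = df, p = p, n = n),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Pearson fit: r = %.2f, adj. R2 = %.2f, t(%d) = %.2f, p = %s, n = %d\n",
              x$r, x$r2_adj, x$df, x$t, format.pval(x$p, digits = 3),
              x$n))
  invisible(x)
}

#' Compare two overlapping dependent correlations
#'
#' Tests whether two models' correlations with the same observed data
#' differ, accounting for the dependence induced by the shared variable and
#' by the correlation between the two prediction vectors. This is Dunn and
#' Clark's z on the Fisher-transformed correlations, with Hittner et al.'s
#' modification: the covariance term c is evaluated at the back-transformed
#' mean \eqn{\bar r = \tanh((Z_{12}+Z_{13})/2)} in place of r12 and r13,
#' \deqn{c = \frac{r_{23}(1-2\bar r^2) - \tfrac12 \bar r^2 (1 - 2\bar r^2 - r_{23}^2)}{(1-\bar r^2)^2},}
#' \deqn{z = (Z_{12} - Z_{13}) \sqrt{\frac{n-3}{2(1-c)}}.}
#'
#' @param r12 Correlation of the observations with model 1's predictions.
#' @param r13 Correlation of the observations with model 2's predictions.
#' @param r23 Correlation between the two prediction vectors.
#' @param n Number of paired cells (>= 4).
#' @return An object of class `corr_comparison`: list with `r12`, `r13`,
#'   `r23`, `n`, `z` and the two-sided `p`.
#' @examples
#' compare_dependent_correlations(0.89, 0.87, 0.95, 116)
#' @export
compare_dependent_correlations <- function(r12, r13, r23, n) {
  rs <- c(r12 = r12, r13 = r13, r23 = r23)
  if (any(abs(rs) > 1)) stop("correlations must lie in [-1, 1]",
                             call. = FALSE)
  if (abs(r12) == 1 || abs(r13) == 1) {
    stop("Fisher transform undefined at |r| = 1", call. = FALSE)
  }
  if (n < 4L) stop("need n >= 4", call. = FALSE)
  z12 <- atanh(r12)
  z13 <- atanh(r13)
  rbar <- tanh((z12 + z13) / 2)
  c_ <- (r23 * (1 - 2 * rbar^2) -
           0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)) / (1 - rbar^2)^2
  if (z12 == z13) {
    z <- 0
    p <- 1
  } else if (c_ >= 1) {
    # near-collinear correlations: the estimated covariance saturates and
    # the statistic's variance is non-positive; no finite z exists
    z <- NA_real_
    p <- NA_real_
  } else {
    z <- (z12 - z13) * sqrt((n - 3) / (2 * (1 - c_)))
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(r12 = r12, r13 = r13, r23 = r23, n = n, z = z, p = p),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  cat(sprintf("Dependent correlations (Hittner/Dunn-Clark): r12 = %.2f vs r13 = %.2f (r23 = %.2f, n = %d): z = %.2f, p = %s\n",
              x$r12, x$r13, x$r23, x$n, x$z,
              format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Exact binomial test
#'
#' Exact two-sided p value for k successes out of n under a null success
#' probability, by summing the probabilities of all outcomes no more likely
#' than the observed one (the standard two-sided convention).
#'
#' @param k Successes (0..n).
#' @param n Trials (> 0).
#' @param p0 Null probability. Default 0.5.
#' @return Two-sided p value.
#' @examples
#' exact_binomial(48, 97)   # ~1: a 48/97 split is as even as it gets
#' @export
exact_binomial <- function(k, n, p0 = 0.5) {
  if (n <= 0L) stop("undefined for n = 0", call. = FALSE)
  if (k < 0L || k > n) stop("k must lie in 0..n", call. = FALSE)
  stats::binom.test(k, n, p = p0)$p.value
}

#' Exact multinomial goodness-of-fit test
#'
#' Exact p value for an observed count vector under null category
#' probabilities, computed by full enumeration of the outcome space: the p
#' value is the total null probability of all outcome vectors whose
#' probability does not exceed (up to a small relative tolerance) that of
#' the observed vector.
#'
#' @param counts Non-negative integer vector of category counts.
#' @param probs Null probabilities, same length, summing to 1. Default
#'   uniform.
#' @param max_outcomes Enumeration guard: error if the outcome space
#'   exceeds this many vectors (suggesting a Monte-Carlo approximation
#'   instead). The default admits three categories up to n of a few
#'   hundred.
#' @return Exact p value.
#' @examples
#' exact_multinomial(c(5, 5, 5))           # 1
#' exact_multinomial(c(10, 0, 0))          # 3 * (1/3)^10
#' @export
exact_multinomial <- function(counts, probs = NULL,
                              max_outcomes = 5e5) {
  counts <- as.integer(counts)
  if (any(counts < 0L)) stop("counts must be non-negative", call. = FALSE)
  k <- length(counts)
  if (is.null(probs)) probs <- rep(1 / k, k)
  if (length(probs) != k || abs(sum(probs) - 1) > 1e-9 || any(probs < 0)) {
    stop("probs must be non-negative and sum to 1", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0L) stop("undefined for n = 0", call. = FALSE)
  n_outcomes <- choose(n + k - 1, k - 1)
  if (n_outcomes > max_outcomes) {
    stop(sprintf(paste0("outcome space too large for exact enumeration ",
                        "(%g vectors); consider a Monte-Carlo approximation"),
                 n_outcomes), call. = FALSE)
  }
  grid <- compositions(n, k)
  logp <- lgamma(n + 1) - rowSums(lgamma(grid + 1)) +
    as.vector(grid %*% ifelse(probs > 0, log(probs), 0))
  # outcomes requiring a zero-probability category have probability 0
  impossible <- as.vector(grid %*% (probs == 0)) > 0
  logp[impossible] <- -Inf
  obs <- lgamma(n + 1) - sum(lgamma(counts + 1)) +
    sum(counts * ifelse(probs > 0, log(probs), 0))
  if (any(counts[probs == 0] > 0L)) return(0)
  sum(exp(logp[logp <= obs + 1e-7]))
}

# all ordered non-negative integer vectors of length k summing to n
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  out <- lapply(0:n, function(i) {
    cbind(i, compositions(n - i, k - 1L), deparse.level = 0)
  })
  do.call(rbind, out)
}

#' Pooled-variance two-sample t test
#'
#' Student's t with pooled variance and n1 + n2 - 2 degrees of freedom,
#' two-sided.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return List with `t`, `df`, `p`, and the sample means.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  if (stats::var(x) + stats::var(y) == 0) {
    stop("degenerate input: zero pooled variance", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Single-predictor least-squares regression
#'
#' Ordinary least squares of a response on one predictor (numeric, or
#' categorical via dummy coding) with intercept, reporting the overall R
#' squared and F test on the predictor's degrees of freedom.
#'
#' @param y Numeric response.
#' @param x Predictor: numeric vector or factor/character.
#' @return List with `r2`, `F`, `df1`, `df2`, `p`.
#' @export
ols_single_predictor <- function(y, x) {
  if (is.character(x)) x <- factor(x)
  if (stats::var(y) == 0) {
    stop("degenerate input: no response variance", call. = FALSE)
  }
  d <- data.frame(y = y, x = x)
  fit <- stats::lm(y ~ x, data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop("degenerate input: singular design", call. = FALSE)
  }
  s <- summary(fit)
  fs <- s$fstatistic
  if (is.null(fs)) stop("degenerate input: no predictor variance",
                        call. = FALSE)
  list(r2 = s$r.squared, F = unname(fs[1]), df1 = unname(fs[2]),
       df2 = unname(fs[3]),
       p = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)))
}
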