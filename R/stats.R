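# Group-level statistics: exact binomial chance levels, lateralization
# binomial tests with Wilson intervals and FDR control, chi-square
# distribution tests, logistic width regression, and the within-subject
# two-way ANOVA on normalized encoding strengths.

#' Exact cumulative-binomial chance level
#'
#' Evaluates the upper-tail probability
#' P(z) = sum_{i=z}^{n} C(n,i) (1/c)^i ((c-1)/c)^(n-i)
#' of achieving at least z correct classifications by chance among n trials
#' with c equiprobable classes, finds the smallest count z* with P(z*) < p,
#' and reports the chance level as the largest accuracy still consistent
#' with chance, 100 * (z* - 1) / n: decoding is above chance exactly when
#' the observed accuracy exceeds this level. Computed from the exact tail
#' (log-space binomial), no normal approximation.
#'
#' @param c number of classes (>= 2).
#' @param n number of trials.
#' @param p significance level (default 0.05).
#' @return list with `chance_percent` (the chance-level accuracy, %),
#'   `min_significant_count` (z*), `c`, `n`, `p`.
#' @export
chance_level <- function(c, n, p = 0.05) {
  stopifnot(c >= 2, n >= 1, p > 0, p < 1)
  z <- 0:n
  tail_p <- stats::pbinom(z - 1, n, 1 / c, lower.tail = FALSE)  # P(X >= z)
  z_star <- z[which(tail_p < p)[1]]
  list(chance_percent = 100 * (z_star - 1) / n,
       min_significant_count = z_star, c = c, n = n, p = p)
}

#' Two-tailed exact binomial lateralization test
#'
#' Tests whether the observed left-hemisphere share of a set of electrodes
#' deviates from the base-rate left proportion, using the exact two-tailed
#' binomial test (minimum-likelihood convention: all outcomes with point
#' probability no larger than the observed one are summed). The proportion
#' is accompanied by a Wilson score 95% interval.
#'
#' @param left observed left-hemisphere count.
#' @param total total count (>= 1).
#' @param chance base-rate left proportion in (0, 1).
#' @param conf confidence level for the Wilson interval.
#' @return data.frame with `left`, `total`, `proportion`, `chance`,
#'   `p_value`, `ci_low`, `ci_high`.
#' @export
hemisphere_binomial_test <- function(left, total, chance, conf = 0.95) {
  stopifnot(total >= 1, left >= 0, left <= total, chance > 0, chance < 1)
  pv <- stats::binom.test(left, total, chance)$p.value
  ci <- wilson_interval(left, total, conf)
  data.frame(left = left, total = total, proportion = left / total,
             chance = chance, p_value = pv,
             ci_low = ci[1], ci_high = ci[2])
}

# Wilson score interval for a binomial proportion
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ph <- x / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (monotone, each >= the raw value).
#' @export
fdr_correct <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Chi-square distribution test
#'
#' With a matrix, a Pearson chi-square test of independence (no continuity
#' correction); with a vector and null proportions, a goodness-of-fit test
#' against that null. Warns when any expected cell is below 1.
#'
#' @param x counts: a matrix (independence) or vector (goodness of fit).
#' @param p null proportions for the goodness-of-fit case.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
distribution_chi2 <- function(x, p = NULL) {
  res <- if (is.matrix(x)) {
    suppressWarnings(stats::chisq.test(x, correct = FALSE))
  } else {
    if (is.null(p)) p <- rep(1 / length(x), length(x))
    suppressWarnings(stats::chisq.test(x, p = p))
  }
  if (any(res$expected < 1)) warning("expected cell count below 1")
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Logistic regression of top-encoder membership on response width
#'
#' Fits, separately for each phonemic unit, a binomial logistic regression
#' of the per-cluster top-encoder counts (out of the cluster totals) on the
#' cluster response widths (ms, end - start; right-censored ends are closed
#' at the epoch end upstream and flagged there). Wald p-values are
#' FDR-adjusted across units. Complete separation triggers a ridge-penalized
#' refit with a warning.
#'
#' @param widths numeric vector of cluster response widths (ms).
#' @param counts clusters x units matrix of top-encoder counts.
#' @param totals per-cluster electrode totals.
#' @return object of class `width_regression`: data.frame with `unit`,
#'   `slope`, `se`, `p_value`, `p_fdr`.
#' @export
width_regression <- function(widths, counts, totals) {
  counts <- as.matrix(counts)
  if (length(widths) < 3L) stop("need at least 3 clusters with defined widths")
  stopifnot(nrow(counts) == length(widths), length(totals) == length(widths),
            all(widths > 0), all(counts >= 0), all(counts <= totals))
  units <- colnames(counts) %||% paste0("unit", seq_len(ncol(counts)))
  fit_one <- function(k) {
    yes <- counts[, k]; no <- totals - yes
    fit <- suppressWarnings(stats::glm(cbind(yes, no) ~ widths,
                                       family = stats::binomial()))
    cf <- summary(fit)$coefficients
    if (!fit$converged || abs(cf["widths", "Estimate"]) > 20) {
      warning("separation in unit ", units[k], "; ridge-penalized refit used")
      rg <- ridge_logistic(widths, yes, no)
      return(c(rg$slope, rg$se, rg$p))
    }
    c(cf["widths", "Estimate"], cf["widths", "Std. Error"],
      cf["widths", "Pr(>|z|)"])
  }
  est <- t(vapply(seq_along(units), fit_one, numeric(3)))
  out <- data.frame(unit = units, slope = est[, 1], se = est[, 2],
                    p_value = est[, 3], p_fdr = fdr_correct(est[, 3]))
  class(out) <- c("width_regression", "data.frame")
  out
}

# small L2-penalized logistic IRLS for the separated case (one predictor)
ridge_logistic <- function(x, yes, no, lambda = 1e-2, max_iter = 100L) {
  X <- cbind(1, scale(x)[, 1])
  n <- yes + no
  beta <- c(stats::qlogis(pmin(pmax(sum(yes) / sum(n), 1e-3), 1 - 1e-3)), 0)
  pen <- diag(c(0, lambda))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- n * mu * (1 - mu)
    grad <- crossprod(X, yes - n * mu) - pen %*% beta
    H <- crossprod(X, X * w) + pen
    step <- solve(H, grad)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < 1e-10) break
  }
  se <- sqrt(diag(solve(H)))
  slope <- beta[2] / stats::sd(x)          # back to the original x scale
  se_slope <- se[2] / stats::sd(x)
  z <- beta[2] / se[2]
  list(slope = slope, se = se_slope, p = 2 * stats::pnorm(-abs(z)))
}

#' Within-subject two-way ANOVA on normalized encoding strength
#'
#' Normalizes encoding strengths within each phonemic unit by the maximum
#' strength of any electrode for that unit, then fits a two-way ANOVA with
#' hemisphere and phonemic unit (and their interaction) as factors.
#' Interaction coefficients are reported per unit as the effect of
#' left-hemisphere placement.
#'
#' @param strengths data.frame with columns `electrode`, `hemisphere`
#'   ("L"/"R"), `unit`, `strength`.
#' @return list with `anova` (data.frame: term, df, F, p), `coefficients`
#'   (named numeric: hemisphere-by-unit interaction coefficients), `data`
#'   (the normalized input).
#' @export
within_subject_anova <- function(strengths) {
  need <- c("electrode", "hemisphere", "unit", "strength")
  stopifnot(all(need %in% names(strengths)))
  d <- strengths
  if (length(unique(d$hemisphere)) < 2L || length(unique(d$unit)) < 2L) {
    stop("need both hemispheres and at least two phonemic units")
  }
  if (any(table(d$hemisphere, d$unit) == 0)) {
    stop("empty hemisphere x unit cell")
  }
  d$norm <- stats::ave(d$strength, d$unit, FUN = function(v) v / max(v))
  d$hemisphere <- stats::relevel(factor(d$hemisphere), ref = "R")
  d$unit <- factor(d$unit)
  if (stats::var(d$norm) < 1e-16) {
    # no variation: every effect is exactly null
    terms <- c("hemisphere", "unit", "hemisphere:unit")
    return(list(
      anova = data.frame(term = terms, df = NA_integer_, F = 0, p_value = 1),
      coefficients = stats::setNames(
        rep(0, nlevels(d$unit)),
        c("hemisphereL", paste0("hemisphereL:unit",
                                levels(d$unit)[-1]))),
      data = d))
  }
  fit <- stats::lm(norm ~ hemisphere * unit, data = d)
  a <- NULL
  if (requireNamespace("car", quietly = TRUE)) {
    a <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
  }
  if (is.null(a)) a <- stats::anova(fit)
  at <- data.frame(term = rownames(a), df = a$Df, F = a$`F value`,
                   p_value = a$`Pr(>F)`)
  # a term with zero sum of squares carries no evidence against the null
  at$p_value[is.nan(at$p_value)] <- 1
  cf <- stats::coef(fit)
  ix <- grep("^hemisphereL($|:)", names(cf))
  list(anova = at, coefficients = cf[ix], data = d)
}
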