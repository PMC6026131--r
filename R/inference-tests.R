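#' @title Factor tests, post-hoc contrasts, dispersion and power
#' @name pialnet-tests
#' @description Drop-one-factor likelihood-ratio tests, Tukey-style
#'   single-step post-hoc contrasts, the Pearson chi-square
#'   overdispersion check, the LMA-vs-PA least-squares regression and the
#'   minimal-detectable-effect-size power computation.
NULL

#' Likelihood-ratio test between nested count-model fits
#'
#' The statistic is twice the difference of maximised marginal
#' log-likelihoods, referred to a chi-square distribution with degrees of
#' freedom equal to the difference in fixed-parameter counts.
#'
#' @param full,reduced [PialFit] objects; `reduced`'s terms must be a
#'   subset of `full`'s, fitted to the same rows with the same random
#'   structure, and both must have converged.
#' @param factorDropped optional label of the dropped factor.
#' @return an object of class `LRTResult` with `statistic`, `df`,
#'   `p_value`, `factor_dropped`.
#' @export
likelihoodRatioTest <- function(full, reduced, factorDropped = NULL) {
  stopifnot(is(full, "PialFit"), is(reduced, "PialFit"))
  if (!full@converged || !reduced@converged)
    stop("both fits must have converged")
  if (!all(reduced@terms %in% full@terms))
    stop("models are not nested: reduced terms are not a subset")
  if (full@nObs != reduced@nObs)
    stop("models were fitted to different numbers of rows")
  if (is.null(factorDropped))
    factorDropped <- paste(setdiff(full@terms, reduced@terms),
                           collapse = "+")
  stat <- 2 * (full@logLik - reduced@logLik)
  if (stat < -1e-6)
    stop("negative deviance difference (", format(stat),
         "); models appear non-nested or unconverged")
  stat <- max(stat, 0)
  df <- full@nFixed - reduced@nFixed
  p <- if (df == 0) as.numeric(stat <= 1e-8) else
    pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = as.integer(df), p_value = p,
                 factor_dropped = factorDropped), class = "LRTResult")
}

#' @export
print.LRTResult <- function(x, ...) {
  cat(sprintf("LRT drop %s: chi2(%d) = %.4f, p = %.4g\n",
              x$factor_dropped, x$df, x$statistic, x$p_value))
  invisible(x)
}

factorEffects <- function(fit, factor) {
  levs <- fit@factorInfo[[factor]]
  if (is.null(levs) || length(levs) < 2)
    stop("factor '", factor, "' has fewer than 2 levels in the fit")
  cn <- names(fit@coef)
  eff <- matrix(0, length(levs), length(cn),
                dimnames = list(levs, cn))
  for (l in levs[-1]) {
    nm <- paste0(factor, l)
    if (!nm %in% cn)
      stop("coefficient ", nm, " not found; was '", factor,
           "' in the fitted terms?")
    eff[l, nm] <- 1
  }
  eff
}

#' Tukey-style post-hoc contrasts of a factor
#'
#' All pairwise level contrasts of a fitted factor on the link (log)
#' scale, with single-step family-wise adjustment by the max-|z|
#' multivariate-normal reference, computed by seeded Monte Carlo from the
#' contrasts' joint normal distribution (the z-based analogue of Tukey's
#' HSD appropriate for mixed-model contrasts).
#'
#' @param fit a converged [PialFit].
#' @param factor factor name (e.g. `"R"` for region).
#' @param nDraws Monte-Carlo draws for the max-|z| reference.
#' @param seed RNG seed for the draws.
#' @return an object of class `PosthocResult`: data.frame with columns
#'   `contrast`, `estimate`, `se`, `z`, `p_raw`, `p_adj`.
#' @export
tukeyPosthoc <- function(fit, factor = "R", nDraws = 1e5, seed = 1L) {
  stopifnot(is(fit, "PialFit"))
  if (!fit@converged) stop("fit did not converge; refusing post-hoc tests")
  eff <- factorEffects(fit, factor)
  levs <- rownames(eff)
  pairs <- utils::combn(levs, 2)
  Cm <- t(apply(pairs, 2, function(pr) eff[pr[1], ] - eff[pr[2], ]))
  rownames(Cm) <- apply(pairs, 2, paste, collapse = " - ")
  est <- as.numeric(Cm %*% fit@coef)
  V <- Cm %*% fit@vcov %*% t(Cm)
  se <- sqrt(pmax(diag(V), 0))
  z <- est / se
  Rcor <- V / outer(se, se)
  Rcor[!is.finite(Rcor)] <- 0
  diag(Rcor) <- 1
  set.seed(seed)
  ch <- tryCatch(chol(Rcor), error = function(e)
    chol(Rcor + diag(1e-8, nrow(Rcor))))
  draws <- matrix(rnorm(nDraws * nrow(Cm)), nDraws) %*% ch
  maxabs <- apply(abs(draws), 1, max)
  pRaw <- 2 * pnorm(-abs(z))
  pAdj <- vapply(z, function(zi) mean(maxabs >= abs(zi)), numeric(1))
  pAdj <- pmax(pAdj, pRaw)
  structure(data.frame(contrast = rownames(Cm), estimate = est, se = se,
                       z = z, p_raw = pRaw, p_adj = pAdj,
                       stringsAsFactors = FALSE),
            class = c("PosthocResult", "data.frame"))
}

#' Pearson chi-square overdispersion check
#'
#' The sum of squared Pearson residuals referred to a chi-square with
#' `n_obs - n_fixed` degrees of freedom; both one-sided tail
#' probabilities are reported (residual variance exceeding the mean, i.e.
#' overdispersion, and falling below it).
#'
#' @param fit a converged [PialFit] with more rows than fixed parameters.
#' @return an object of class `DispersionResult` with `statistic`, `df`,
#'   `ratio`, `p_over`, `p_under`.
#' @export
dispersionCheck <- function(fit) {
  stopifnot(is(fit, "PialFit"))
  if (!fit@converged) stop("fit did not converge")
  if (fit@nObs <= fit@nFixed)
    stop("no residual degrees of freedom")
  if (all(abs(fit@pearson) < 1e-12))
    stop("degenerate residuals: fitted values equal observations everywhere")
  stat <- sum(fit@pearson^2)
  df <- fit@nObs - fit@nFixed
  structure(list(statistic = stat, df = as.integer(df),
                 ratio = stat / df,
                 p_over = pchisq(stat, df, lower.tail = FALSE),
                 p_under = pchisq(stat, df)),
            class = "DispersionResult")
}

#' @export
print.DispersionResult <- function(x, ...) {
  cat(sprintf(
    "Dispersion: chi2(%d) = %.3f (ratio %.3f); p_over = %.4g, p_under = %.4g\n",
    x$df, x$statistic, x$ratio, x$p_over, x$p_under))
  invisible(x)
}

#' Least-squares regression of LMA on PA counts
#'
#' Ordinary least squares of per-animal LMA totals on PA totals, with a
#' t-test on the slope (n - 2 df) and Bonferroni adjustment over
#' `kComparisons` regressions (pooled/plucked/sham in the standard
#' analysis).
#'
#' @param pa,lma numeric vectors of per-animal totals over the stated
#'   regions.
#' @param kComparisons Bonferroni family size.
#' @return an object of class `RegressionResult` with `slope`,
#'   `intercept`, `r_squared`, `t`, `df`, `p_raw`, `p_adj`, `n`.
#' @export
lmaPaRegression <- function(pa, lma, kComparisons = 1) {
  stopifnot(length(pa) == length(lma))
  if (length(pa) < 3) stop("at least 3 animals are required")
  if (stats::var(pa) == 0) stop("zero variance in the PA predictor")
  if (stats::var(lma) == 0) {
    out <- list(slope = 0, intercept = mean(lma), r_squared = 0,
                t = 0, df = length(pa) - 2L, p_raw = 1, p_adj = 1,
                n = length(pa))
    return(structure(out, class = "RegressionResult"))
  }
  m <- lm(lma ~ pa)
  sm <- summary(m)
  tval <- sm$coefficients["pa", "t value"]
  pRaw <- sm$coefficients["pa", "Pr(>|t|)"]
  structure(list(slope = unname(coef(m)["pa"]),
                 intercept = unname(coef(m)["(Intercept)"]),
                 r_squared = sm$r.squared, t = tval,
                 df = m$df.residual, p_raw = pRaw,
                 p_adj = min(1, kComparisons * pRaw), n = length(pa)),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf(
    "OLS: y = %.3f + %.3f x, R2 = %.3f, t(%d) = %.2f, p = %.4g (adj %.4g)\n",
    x$intercept, x$slope, x$r_squared, x$df, x$t, x$p_raw, x$p_adj))
  invisible(x)
}

#' Minimal detectable effect size of a two-sample t-test
#'
#' The smallest Cohen's d at which a two-sample t-test with noncentrality
#' `d * sqrt(n1 n2 / (n1 + n2))` and `n1 + n2 - 2` degrees of freedom
#' attains the requested power at level `alpha`, solved by bisection to
#' 1e-6.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param alpha significance level.
#' @param power requested power (1 - beta).
#' @param tails 1 or 2.
#' @return Cohen's d (0, with a warning, when the requested power does not
#'   exceed the test size).
#' @examples
#' detectableEffectSize(10, 9, alpha = 0.05, power = 0.8, tails = 1)
#' @export
detectableEffectSize <- function(n1, n2, alpha = 0.05, power = 0.8,
                                 tails = 1) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1, power > 0, power < 1,
            tails %in% c(1, 2))
  df <- n1 + n2 - 2
  mult <- sqrt(n1 * n2 / (n1 + n2))
  powerAt <- function(d) {
    ncp <- d * mult
    if (tails == 1) {
      crit <- qt(1 - alpha, df)
      1 - pt(crit, df, ncp = ncp)
    } else {
      crit <- qt(1 - alpha / 2, df)
      (1 - pt(crit, df, ncp = ncp)) + pt(-crit, df, ncp = ncp)
    }
  }
  if (powerAt(0) >= power) {
    warning("requested power does not exceed the test size; d = 0")
    return(0)
  }
  lo <- 0; hi <- 1
  while (powerAt(hi) < power) hi <- hi * 2
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (powerAt(mid) < power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
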