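# Count-model fitting, factor tests, post-hoc contrasts, dispersion,
# regression and power.

toyTable <- function() {
  data.frame(animal_id = rep(sprintf("m%d", 1:3), each = 2),
             group = "sham", sex = "M", age_days = 50,
             region = rep(c("barrels", "visual"), 3), area_mm2 = 1,
             count = c(3, 1, 4, 2, 5, 1), flavor = "pa",
             stringsAsFactors = FALSE)
}

test_that("equal counts collapse to a degenerate intercept-only fit", {
  tab <- data.frame(animal_id = sprintf("m%d", 1:6), group = "sham",
                    sex = "M", age_days = 50, region = "barrels",
                    area_mm2 = 1, count = 5, flavor = "pa")
  fit <- fitPoissonGlmm(tab, terms = character(0))
  expect_equal(unname(fit@coef[1]), log(5), tolerance = 1e-6)
  expect_lt(fit@sigmaU, 1e-4)
})

test_that("with sigma_u fixed at zero the fit matches the IRLS oracle", {
  tab <- simulateCountTable(generatorParams(sigmaU = 0.3, seed = 91))
  fit <- fitPoissonGlmm(tab, terms = c("S", "R"), sigmaU = 0)
  df <- transform(tab,
                  group = factor(group, c("sham", "plucked")),
                  region = factor(region, c("barrels", "auditory",
                                            "forelimb", "hindlimb",
                                            "visual")))
  g <- stats::glm(count ~ group + region, family = stats::poisson,
                  offset = log(area_mm2), data = df)
  expect_lt(max(abs(unname(fit@coef) - unname(coef(g)))), 1e-6)
  expect_equal(fit@logLik, as.numeric(stats::logLik(g)), tolerance = 1e-8)
})

test_that("the mixed likelihood approaches the GLM limit as sigma -> 0", {
  tab <- toyTable()
  f0 <- fitPoissonGlmm(tab, terms = "R", sigmaU = 0)
  f1 <- fitPoissonGlmm(tab, terms = "R", sigmaU = 1e-6)
  expect_lt(abs(f0@logLik - f1@logLik), 1e-6)
})

test_that("mixed-model fits agree with an independent GLMM package", {
  skip_if_not_installed("lme4")
  tab <- simulateCountTable(generatorParams(seed = 93))
  fit <- fitPoissonGlmm(tab, terms = c("S", "R"))
  df <- transform(tab,
                  group = factor(group, c("sham", "plucked")),
                  region = factor(region, c("barrels", "auditory",
                                            "forelimb", "hindlimb",
                                            "visual")))
  g <- lme4::glmer(count ~ group + region + (1 | animal_id),
                   family = stats::poisson, offset = log(area_mm2),
                   data = df, nAGQ = 15)
  expect_lt(max(abs(unname(fit@coef) - unname(lme4::fixef(g)))), 1e-3)
  expect_equal(unname(fit@sigmaU),
               sqrt(unname(lme4::VarCorr(g)$animal_id[1, 1])),
               tolerance = 1e-3)
  # log-likelihood differences between nested fits agree (lme4 reports
  # the likelihood up to a different additive constant)
  red <- fitPoissonGlmm(tab, terms = "R")
  gr <- lme4::glmer(count ~ region + (1 | animal_id),
                    family = stats::poisson, offset = log(area_mm2),
                    data = df, nAGQ = 15)
  expect_equal(2 * (fit@logLik - red@logLik),
               2 * (as.numeric(stats::logLik(g)) -
                      as.numeric(stats::logLik(gr))),
               tolerance = 1e-3)
})

test_that("fits are invariant to row reordering", {
  tab <- simulateCountTable(generatorParams(seed = 95))
  f1 <- fitPoissonGlmm(tab, terms = c("S", "R"))
  set.seed(1)
  f2 <- fitPoissonGlmm(tab[sample(nrow(tab)), ], terms = c("S", "R"))
  expect_equal(f1@logLik, f2@logLik, tolerance = 1e-6)
  expect_lt(max(abs(f1@coef - f2@coef)), 1e-3)
})

test_that("likelihood-ratio tests report the drop-one degrees of freedom", {
  tab <- simulateCountTable(generatorParams(seed = 97))
  full <- fitPoissonGlmm(tab)
  same <- likelihoodRatioTest(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  redSR <- fitPoissonGlmm(tab, terms = c("S", "Y", "YxS", "G", "R"))
  t1 <- likelihoodRatioTest(full, redSR, "SxR")
  expect_identical(t1$df, 4L)
  redS <- fitPoissonGlmm(tab, terms = c("Y", "YxS", "G", "R", "SxR"))
  t2 <- likelihoodRatioTest(full, redS, "S")
  expect_identical(t2$df, 1L)
  expect_gte(t1$statistic, 0)
  # non-nested pairs are refused
  fa <- fitPoissonGlmm(tab, terms = c("S"))
  fb <- fitPoissonGlmm(tab, terms = c("G"))
  expect_error(likelihoodRatioTest(fa, fb), "not nested")
})

test_that("post-hoc contrasts reduce to the z-test for two levels", {
  tab <- simulateCountTable(generatorParams(seed = 99))
  tab <- tab[tab$region %in% c("barrels", "visual"), ]
  fit <- fitPoissonGlmm(tab, terms = c("R"))
  ph <- tukeyPosthoc(fit, "R", nDraws = 2e5, seed = 7)
  expect_identical(nrow(ph), 1L)
  expect_equal(ph$p_adj, ph$p_raw, tolerance = 0.01)
  expect_gte(ph$p_adj, ph$p_raw)
})

test_that("five-region post-hoc families control the adjusted p-values", {
  tab <- simulateCountTable(generatorParams(seed = 101))
  fit <- fitPoissonGlmm(tab, terms = c("S", "R"))
  ph <- tukeyPosthoc(fit, "R", nDraws = 5e4, seed = 8)
  expect_identical(nrow(ph), 10L)
  expect_true(all(ph$p_adj >= ph$p_raw))
  expect_true(all(ph$p_adj <= 1))
  # a contrast with (near) zero estimate has adjusted p near 1
  phz <- ph[which.min(abs(ph$z)), ]
  if (abs(phz$z) < 0.05) expect_gt(phz$p_adj, 0.95)
})

test_that("dispersion check flags degenerate residuals and reports tails", {
  tab <- simulateCountTable(generatorParams(sigmaU = 0, seed = 103))
  fit <- fitPoissonGlmm(tab, terms = c("S", "R"), sigmaU = 0)
  d <- dispersionCheck(fit)
  expect_identical(d$df, fit@nObs - fit@nFixed)
  expect_equal(d$statistic, sum(fit@pearson^2))
  expect_equal(d$p_over + d$p_under, 1, tolerance = 1e-12)
  perfect <- fit
  perfect@pearson <- rep(0, fit@nObs)
  expect_error(dispersionCheck(perfect), "degenerate")
})

test_that("least-squares regression matches closed forms", {
  x <- c(1, 2, 3, 5, 8)
  # exact collinearity legitimately trips lm's perfect-fit warning
  r <- suppressWarnings(lmaPaRegression(x, 2 * x + 1))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  rc <- lmaPaRegression(x, rep(4, 5), kComparisons = 3)
  expect_equal(rc$slope, 0)
  expect_equal(rc$r_squared, 0)
  expect_equal(rc$p_adj, 1)
  set.seed(105)
  px <- rnorm(10); py <- rnorm(10)
  r2 <- lmaPaRegression(px, py, kComparisons = 3)
  # normal-equations oracle
  bh <- solve(t(cbind(1, px)) %*% cbind(1, px), t(cbind(1, px)) %*% py)
  expect_lt(abs(r2$intercept - bh[1]), 1e-10)
  expect_lt(abs(r2$slope - bh[2]), 1e-10)
  expect_equal(r2$p_adj, min(1, 3 * r2$p_raw))
  expect_error(lmaPaRegression(rep(2, 5), py[1:5]), "zero variance")
})

test_that("detectable effect size behaves like the noncentral-t solution", {
  d <- detectableEffectSize(10, 9, alpha = 0.05, power = 0.8, tails = 1)
  normApprox <- (qnorm(0.95) + qnorm(0.8)) * sqrt(1 / 10 + 1 / 9)
  expect_gt(d, normApprox)  # t reference is strictly wider than normal
  expect_warning(d0 <- detectableEffectSize(10, 9, alpha = 0.5,
                                            power = 0.5, tails = 1),
                 "power")
  expect_equal(d0, 0)
  # strictly decreasing in n, increasing in power
  d2 <- detectableEffectSize(20, 18, alpha = 0.05, power = 0.8, tails = 1)
  expect_lt(d2, d)
  d3 <- detectableEffectSize(10, 9, alpha = 0.05, power = 0.9, tails = 1)
  expect_gt(d3, d)
  # two-tailed is harder to power than one-tailed
  d4 <- detectableEffectSize(10, 9, alpha = 0.05, power = 0.8, tails = 2)
  expect_gt(d4, d)
})

test_that("rank-deficient designs are refused with the aliased term", {
  tab <- simulateCountTable(generatorParams(seed = 107))
  tab$group <- "sham"  # S has one level; SxR columns vanish
  tab2 <- tab
  tab2$age_days <- 50  # constant age with YxS still fine; Yc all zero
  expect_error(fitPoissonGlmm(tab2, terms = c("Y", "R")), "aliased")
})
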