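#' @title Poisson mixed count model
#' @name pialnet-glmm
#' @description The count model at the heart of the analysis: counts
#'   within an animal-by-region cell are Poisson with log-intensity
#'   `X beta + log(area) + u_animal`, where `u_animal ~ N(0, sigma_u^2)`
#'   is a per-animal random intercept shared across regions.  The marginal
#'   likelihood (Poisson likelihood integrated over the random intercept)
#'   is maximised directly, using adaptive Gauss--Hermite quadrature.
NULL

# Gauss-Hermite nodes/weights (physicists' convention) via Golub-Welsch
gaussHermite <- function(n) {
  if (n == 1) return(list(z = 0, w = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(z = e$values[ord], w = sqrt(pi) * e$vectors[1, ord]^2)
}

TERM_LABELS <- c(S = "S", Y = "Yc", YxS = "S:Yc", G = "G", R = "R",
                 SxR = "S:R")

# model frame + design matrix for a count table
glmmDesign <- function(table, terms) {
  stopifnot(all(c("animal_id", "group", "sex", "age_days", "region",
                  "area_mm2", "count") %in% names(table)))
  if (!nrow(table)) stop("empty count table")
  bad <- setdiff(terms, names(TERM_LABELS))
  if (length(bad)) stop("unknown model term(s): ", paste(bad, collapse = ", "))
  df <- table[order(table$animal_id), , drop = FALSE]
  rl <- sort(unique(df$region))
  if ("barrels" %in% rl) rl <- c("barrels", setdiff(rl, "barrels"))
  df$R <- factor(df$region, levels = rl)
  df$S <- factor(df$group, levels = intersect(c("sham", "plucked"),
                                              unique(df$group)))
  df$G <- factor(df$sex, levels = intersect(c("M", "F"), unique(df$sex)))
  df$Yc <- df$age_days - mean(df$age_days)
  # explicit treatment-coded columns (refs barrels/sham/M), so that
  # dropping a single term removes exactly its columns
  cols <- list("(Intercept)" = rep(1, nrow(df)))
  sInd <- if (nlevels(df$S) > 1) as.numeric(df$S == levels(df$S)[2]) else
    NULL
  if ("S" %in% terms && !is.null(sInd))
    cols[[paste0("S", levels(df$S)[2])]] <- sInd
  if ("Y" %in% terms) cols[["Yc"]] <- df$Yc
  if ("YxS" %in% terms && !is.null(sInd))
    cols[[paste0("S", levels(df$S)[2], ":Yc")]] <- sInd * df$Yc
  if ("G" %in% terms && nlevels(df$G) > 1)
    cols[[paste0("G", levels(df$G)[2])]] <-
      as.numeric(df$G == levels(df$G)[2])
  if ("R" %in% terms)
    for (l in levels(df$R)[-1])
      cols[[paste0("R", l)]] <- as.numeric(df$R == l)
  if ("SxR" %in% terms && !is.null(sInd))
    for (l in levels(df$R)[-1])
      cols[[paste0("S", levels(df$S)[2], ":R", l)]] <-
        sInd * as.numeric(df$R == l)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  animals <- unique(df$animal_id)
  idx <- match(df$animal_id, animals)
  gstart <- vapply(seq_along(animals), function(a)
    min(which(idx == a)) - 1L, integer(1))
  gend <- vapply(seq_along(animals), function(a)
    max(which(idx == a)) - 1L, integer(1))
  list(df = df, X = X, y = as.numeric(df$count),
       off = log(df$area_mm2), gstart = gstart, gend = gend,
       animals = animals,
       factorInfo = list(
         R = levels(df$R), S = levels(df$S), G = levels(df$G)))
}

numericHessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  hh <- pmax(abs(x), 1) * h
  for (i in seq_len(p)) for (j in i:p) {
    if (i == j) {
      xp <- x; xm <- x
      xp[i] <- x[i] + hh[i]; xm[i] <- x[i] - hh[i]
      H[i, i] <- (f(xp) - 2 * f(x) + f(xm)) / hh[i]^2
    } else {
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[c(i, j)] <- x[c(i, j)] + hh[c(i, j)]
      xmm[c(i, j)] <- x[c(i, j)] - hh[c(i, j)]
      xpm[i] <- x[i] + hh[i]; xpm[j] <- x[j] - hh[j]
      xmp[i] <- x[i] - hh[i]; xmp[j] <- x[j] + hh[j]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * hh[i] * hh[j])
    }
  }
  H
}

#' Fit the Poisson mixed count model
#'
#' Maximises the marginal likelihood of the Poisson count model with
#' log-area offset and a per-animal Gaussian random intercept, by adaptive
#' Gauss--Hermite quadrature (default 15 nodes; 1 node is the Laplace
#' approximation) with quasi-Newton outer optimisation.  Starting values
#' come from the `sigma_u = 0` Poisson regression.  The full model of the
#' analysis has `terms = c("S", "Y", "YxS", "G", "R", "SxR")` with
#' treatment coding referenced at barrels/sham/M and age centred at the
#' cohort mean.
#'
#' @param table a count table from [buildCountTable()] or
#'   [simulateCountTable()].
#' @param terms character subset of `c("S", "Y", "YxS", "G", "R", "SxR")`
#'   (deprivation group, centred age, their interaction, sex, region,
#'   group-by-region); the intercept and the log-area offset are always
#'   included.
#' @param nAGQ number of adaptive quadrature nodes.
#' @param sigmaU `NULL` to estimate the random-intercept sd, or a fixed
#'   non-negative value (0 reduces the model to a plain Poisson GLM).
#' @param reltol relative log-likelihood convergence tolerance.
#' @return a [PialFit].
#' @examples
#' tab <- simulateCountTable(generatorParams(sigmaU = 0.2), seed = 1)
#' fit <- fitPoissonGlmm(tab, terms = c("S", "R"))
#' fit
#' @export
fitPoissonGlmm <- function(table, terms = c("S", "Y", "YxS", "G", "R",
                                            "SxR"),
                           nAGQ = 15, sigmaU = NULL, reltol = 1e-8) {
  d <- glmmDesign(table, terms)
  gh <- gaussHermite(nAGQ)
  p <- ncol(d$X)
  fit0 <- glm.fit(d$X, d$y, offset = d$off, family = poisson())
  beta0 <- coef(fit0)
  estimateSigma <- is.null(sigmaU)
  nll <- function(par) {
    beta <- par[seq_len(p)]
    sig <- if (estimateSigma) exp(par[p + 1]) else sigmaU
    cppGlmmNll(beta, sig, d$X, d$off, d$y, d$gstart, d$gend, gh$z, gh$w)
  }
  if (estimateSigma) {
    par0 <- c(beta0, log(0.3))
    lower <- c(rep(-Inf, p), log(1e-6))
    upper <- c(rep(Inf, p), log(10))
  } else {
    par0 <- beta0
    lower <- rep(-Inf, p); upper <- rep(Inf, p)
  }
  opt <- nlminb(par0, nll, lower = lower, upper = upper,
                control = list(rel.tol = reltol, iter.max = 500,
                               eval.max = 2000))
  par <- unname(opt$par)
  beta <- setNames(par[seq_len(p)], colnames(d$X))
  sig <- if (estimateSigma) exp(par[p + 1]) else sigmaU
  if (estimateSigma && par[p + 1] <= log(1e-6) + 1e-6) sig <- 0
  ll <- unname(-nll(par))
  # covariance of the fixed effects from the observed information
  useSigma <- estimateSigma && sig > 1e-4
  hx <- if (useSigma) par else par[seq_len(p)]
  hf <- if (useSigma) nll else function(b) {
    cppGlmmNll(b, sig, d$X, d$off, d$y, d$gstart, d$gend, gh$z, gh$w)
  }
  H <- numericHessian(hf, hx)
  V <- tryCatch(solve(H)[seq_len(p), seq_len(p), drop = FALSE],
                error = function(e) matrix(NA_real_, p, p))
  if (anyNA(V) || any(!is.finite(diag(V))) || any(diag(V) < 0)) {
    Hb <- numericHessian(function(b)
      cppGlmmNll(b, sig, d$X, d$off, d$y, d$gstart, d$gend, gh$z, gh$w),
      par[seq_len(p)])
    V <- tryCatch(solve(Hb), error = function(e) matrix(NA_real_, p, p))
  }
  dimnames(V) <- list(colnames(d$X), colnames(d$X))
  se <- sqrt(pmax(diag(V), 0))
  modes <- cppGlmmModes(par[seq_len(p)], sig, d$X, d$off, d$y, d$gstart,
                        d$gend, gh$z, gh$w)
  uRow <- modes[match(d$df$animal_id, d$animals)]
  fitted <- exp(as.numeric(d$X %*% par[seq_len(p)]) + d$off + uRow)
  pearson <- (d$y - fitted) / sqrt(fitted)
  converged <- opt$convergence == 0 && all(is.finite(beta)) &&
    is.finite(ll)
  new("PialFit", coef = beta, se = se, vcov = V, sigmaU = sig,
      logLik = ll, fitted = fitted, pearson = pearson,
      converged = converged, nObs = nrow(d$df), nFixed = as.integer(p),
      terms = as.character(terms), factorInfo = d$factorInfo,
      table = d$df)
}

#' Simulate a count table directly from the count model
#'
#' Draws per-animal random intercepts and Poisson counts with the
#' intensities and cohort layout of a [GeneratorParams] (region areas taken
#' as their targets), without constructing network geometry.  Used for
#' calibration and power experiments on the inference machinery.
#'
#' @param params a [GeneratorParams].
#' @param seed RNG seed (defaults to the params seed).
#' @param rates `"pa"` to use the global PA intensity, `"lma"` for the
#'   per-region LMA intensities.
#' @return a count table data.frame as from [buildCountTable()].
#' @export
simulateCountTable <- function(params = generatorParams(), seed = NULL,
                               rates = c("pa", "lma")) {
  rates <- match.arg(rates)
  stopifnot(is(params, "GeneratorParams"))
  if (!is.null(seed)) set.seed(seed) else set.seed(params@seed)
  n <- params@nSham + params@nPlucked
  if (n == 0) stop("cohort size is zero")
  groups <- c(rep("sham", params@nSham), rep("plucked", params@nPlucked))
  sexes <- rep(c("F", "M"), length.out = n)
  ages <- runif(n, params@ageRangeDays[1], params@ageRangeDays[2])
  areas <- params@regionAreasMm2
  rids <- names(areas)
  rows <- lapply(seq_len(n), function(i) {
    u <- rnorm(1, 0, params@sigmaU)
    lam <- vapply(rids, function(r) {
      base <- if (rates == "pa") params@lambdaPaPerMm2
              else params@lmaRatePerMm2[[r]]
      m <- if (groups[i] == "plucked" && r == "barrels")
        params@deprivationMultiplier else 1
      base * areas[[r]] * exp(u) * m
    }, numeric(1))
    data.frame(animal_id = sprintf("m%03d", i), group = groups[i],
               sex = sexes[i], age_days = ages[i], region = rids,
               area_mm2 = as.numeric(areas[rids]),
               count = rpois(length(rids), lam), flavor = rates,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
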