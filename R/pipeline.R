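#' @title End-to-end analysis pipeline
#' @name pialnet-pipeline
#' @description Sequences the full analysis: simulate (or accept) a
#'   cohort, validate, decompose, tile, assign, build count tables per
#'   flavor, fit the full mixed model, run drop-one-factor
#'   likelihood-ratio tests, post-hoc region contrasts, dispersion checks,
#'   the LMA-vs-PA regressions and the power summary.
NULL

FULL_TERMS <- c("S", "Y", "YxS", "G", "R", "SxR")
LRT_FACTORS <- c("S", "SxR", "Y", "G")

defaultPipelineConfig <- function() {
  list(generator = list(),
       analysis = list(nearCutoffMm = 0.3, nAGQ = 15, tukeyDraws = 1e5,
                       flavors = c("pa", "lma"), omit = NULL),
       report = list())
}

#' Run the full analysis pipeline
#'
#' @param config `NULL` for defaults, a list, or the path of a YAML file
#'   with entries `generator` (fields of [generatorParams()]) and
#'   `analysis` (`nearCutoffMm`, `nAGQ`, `tukeyDraws`, `flavors`, `omit`).
#' @param seed top-level seed; overrides the generator seed and
#'   deterministically spawns per-stage substreams.
#' @param cohort optionally, an existing list of [AnimalSample]s to
#'   analyse instead of simulating one.
#' @param outDir optional output directory for CSV/JSON artifacts.
#' @return a report bundle: list with `cohort`, `tables`, `fits`, `lrt`,
#'   `posthoc`, `dispersion`, `regressions`, `power`, `log`.
#' @export
runPipeline <- function(config = NULL, seed = NULL, cohort = NULL,
                        outDir = NULL) {
  cfg <- defaultPipelineConfig()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) cfg <- modifyList(cfg, config)
  gargs <- cfg$generator
  if (!is.null(gargs$regionAreasMm2))
    gargs$regionAreasMm2 <- unlist(gargs$regionAreasMm2)
  if (!is.null(gargs$lmaRatePerMm2))
    gargs$lmaRatePerMm2 <- unlist(gargs$lmaRatePerMm2)
  if (!is.null(seed)) gargs$seed <- seed
  params <- do.call(generatorParams, gargs)
  log <- list(seed = params@seed,
              tukeySeed = deriveSeed(params@seed, 101L))
  if (is.null(cohort)) cohort <- generateCohort(params)
  for (an in cohort) {
    f <- validateNetwork(an@network, an@regions)
    if (nrow(f))
      stop(sprintf("stage validate, animal %s: %s", an@animalId,
                   f$message[1]))
  }
  omit <- cfg$analysis$omit
  if (!is.null(omit)) omit <- as.data.frame(omit)
  flavors <- cfg$analysis$flavors
  tables <- list(); fits <- list(); lrt <- list(); posthoc <- list()
  dispersion <- list()
  for (fl in flavors) {
    tab <- tryCatch(
      buildCountTable(cohort, flavor = fl, omit = omit,
                      nearCutoffMm = cfg$analysis$nearCutoffMm),
      error = function(e)
        stop(sprintf("stage count (%s): %s", fl, conditionMessage(e))))
    tables[[fl]] <- tab
    full <- tryCatch(
      fitPoissonGlmm(tab, terms = FULL_TERMS, nAGQ = cfg$analysis$nAGQ),
      error = function(e)
        stop(sprintf("stage fit (%s): %s", fl, conditionMessage(e))))
    fits[[fl]] <- full
    lt <- lapply(LRT_FACTORS, function(fac) {
      red <- fitPoissonGlmm(tab, terms = setdiff(FULL_TERMS, fac),
                            nAGQ = cfg$analysis$nAGQ)
      likelihoodRatioTest(full, red, factorDropped = fac)
    })
    names(lt) <- LRT_FACTORS
    lrt[[fl]] <- lt
    posthoc[[fl]] <- tukeyPosthoc(full, "R",
                                  nDraws = cfg$analysis$tukeyDraws,
                                  seed = log$tukeySeed)
    dispersion[[fl]] <- dispersionCheck(full)
  }
  # per-animal PA/LMA totals over the somatosensory regions
  statedRegions <- c("barrels", "forelimb", "hindlimb")
  totals <- NULL
  if (all(c("pa", "lma") %in% names(tables))) {
    tp <- tables$pa[tables$pa$region %in% statedRegions, ]
    tl <- tables$lma[tables$lma$region %in% statedRegions, ]
    pa <- tapply(tp$count, tp$animal_id, sum)
    lma <- tapply(tl$count, tl$animal_id, sum)
    ids <- intersect(names(pa), names(lma))
    grp <- vapply(cohort, function(a) a@group, character(1))
    names(grp) <- vapply(cohort, function(a) a@animalId, character(1))
    totals <- data.frame(animal_id = ids, group = grp[ids],
                         pa = as.numeric(pa[ids]),
                         lma = as.numeric(lma[ids]),
                         stringsAsFactors = FALSE)
  }
  regressions <- NULL
  if (!is.null(totals) && nrow(totals) >= 3) {
    regressions <- list(pooled = lmaPaRegression(totals$pa, totals$lma, 3))
    for (g in c("plucked", "sham")) {
      sub <- totals[totals$group == g, ]
      if (nrow(sub) >= 3 && stats::var(sub$pa) > 0)
        regressions[[g]] <- lmaPaRegression(sub$pa, sub$lma, 3)
    }
  }
  power <- list(n1 = params@nSham, n2 = params@nPlucked, alpha = 0.05,
                power = 0.8, tails = 1,
                d = detectableEffectSize(params@nSham, params@nPlucked,
                                         alpha = 0.05, power = 0.8,
                                         tails = 1))
  bundle <- list(params = params, cohort = cohort, tables = tables,
                 fits = fits, lrt = lrt, posthoc = posthoc,
                 dispersion = dispersion, totals = totals,
                 regressions = regressions, power = power, log = log)
  if (!is.null(outDir)) writeBundle(bundle, outDir)
  bundle
}

writeBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (fl in names(bundle$tables))
    utils::write.csv(bundle$tables[[fl]],
                     file.path(outDir, sprintf("counts_%s.csv", fl)),
                     row.names = FALSE)
  tests <- do.call(rbind, lapply(names(bundle$lrt), function(fl)
    do.call(rbind, lapply(bundle$lrt[[fl]], function(t)
      data.frame(flavor = fl, factor = t$factor_dropped,
                 statistic = t$statistic, df = t$df,
                 p_value = t$p_value, stringsAsFactors = FALSE)))))
  utils::write.csv(tests, file.path(outDir, "lrt.csv"), row.names = FALSE)
  fitJson <- lapply(bundle$fits, function(f)
    list(coef = as.list(f@coef), se = as.list(f@se), sigma_u = f@sigmaU,
         loglik = f@logLik, converged = f@converged, n_obs = f@nObs))
  jsonlite::write_json(fitJson, file.path(outDir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(seed = bundle$log$seed,
                            tukey_seed = bundle$log$tukeySeed,
                            power = bundle$power),
                       file.path(outDir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Summarise a pipeline report bundle
#'
#' Human-readable tables: per-region density means by group and flavor,
#' the likelihood-ratio test table, dispersion checks, regression lines
#' and the detectable-effect-size power line.
#'
#' @param bundle a report bundle from [runPipeline()].
#' @return a list with `densities`, `tests`, `dispersion`, `regressions`,
#'   `power` (data.frames / lists).
#' @export
reportSummary <- function(bundle) {
  if (is.null(bundle$tables) || !length(bundle$tables))
    stop("empty report bundle")
  dens <- do.call(rbind, lapply(names(bundle$tables), function(fl) {
    tab <- bundle$tables[[fl]]
    agg <- aggregate(cbind(count, area_mm2) ~ region + group, data = tab,
                     FUN = sum)
    data.frame(flavor = fl, region = agg$region, group = agg$group,
               density_per_mm2 = agg$count / agg$area_mm2,
               stringsAsFactors = FALSE)
  }))
  tests <- do.call(rbind, lapply(names(bundle$lrt), function(fl)
    do.call(rbind, lapply(bundle$lrt[[fl]], function(t)
      data.frame(flavor = fl, factor = t$factor_dropped,
                 statistic = t$statistic, df = t$df, p_value = t$p_value,
                 stringsAsFactors = FALSE)))))
  rownames(tests) <- NULL
  disp <- do.call(rbind, lapply(names(bundle$dispersion), function(fl) {
    d <- bundle$dispersion[[fl]]
    data.frame(flavor = fl, statistic = d$statistic, df = d$df,
               ratio = d$ratio, p_over = d$p_over, p_under = d$p_under,
               stringsAsFactors = FALSE)
  }))
  list(densities = dens, tests = tests, dispersion = disp,
       regressions = bundle$regressions, power = bundle$power)
}
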