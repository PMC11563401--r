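## Stage-one analysis of plot records, per trait and condition: REML fit of
## the randomized-complete-block multi-year model, adjusted genotype means
## (E-BLUEs), variance components, broad-sense heritability, trait
## summaries and the protein/yield deviation indices.

checkPlots <- function(plots, trait) {
  need <- c("genotype", "year", "condition", "replicate")
  if (!all(need %in% names(plots)))
    stopf("plot table must have columns %s", paste(need, collapse = ", "))
  if (!trait %in% names(plots)) stopf("trait '%s' not found in plot table", trait)
  invisible(TRUE)
}

#' Fit the stage-one mixed model for one trait in one condition
#'
#' Model: value = mean + genotype + year + replicate-within-year +
#' genotype-by-year + residual. Year, replicate-within-year and
#' genotype-by-year are always random; the genotype enters either as a
#' fixed effect (to produce E-BLUEs, the adjusted genotype means) or as a
#' random effect (to estimate the genotypic variance that the
#' broad-sense-heritability formula needs). Terms that the design cannot
#' identify (e.g. year effects in a single-year data set) are dropped and
#' their variance reported as 0. Fitting is REML via \pkg{lme4}.
#'
#' @param plots plot-record data.frame (columns genotype, year, condition,
#'   replicate, one column per trait).
#' @param trait trait column to analyse.
#' @param condition condition label to subset on.
#' @param genotypeAs \code{"fixed"} (E-BLUEs) or \code{"random"}
#'   (variance components / heritability).
#' @return A \code{StageOneFit}.
#' @export
fitStageOne <- function(plots, trait, condition,
                        genotypeAs = c("fixed", "random")) {
  genotypeAs <- match.arg(genotypeAs)
  checkPlots(plots, trait)
  d <- plots[plots$condition == condition, , drop = FALSE]
  if (!nrow(d)) stopf("no plots for condition '%s'", condition)
  d <- data.frame(y = d[[trait]],
                  genotype = factor(d$genotype),
                  year = factor(d$year),
                  replicate = factor(d$replicate))
  d <- d[is.finite(d$y), , drop = FALSE]
  nYears <- nlevels(droplevels(d$year))
  nReps <- nlevels(droplevels(d$replicate))
  if (nYears < 2L && nReps < 2L)
    stopf("design with 1 year and 1 replicate: variance components are not identifiable")
  d$yearRep <- interaction(d$year, d$replicate, drop = TRUE)
  terms <- character()
  if (nYears >= 2L) terms <- c(terms, "(1 | year)")
  if (nlevels(d$yearRep) >= 2L) terms <- c(terms, "(1 | yearRep)")
  if (nYears >= 2L) terms <- c(terms, "(1 | genotype:year)")
  if (genotypeAs == "random") terms <- c(terms, "(1 | genotype)")
  fixedPart <- if (genotypeAs == "fixed") "0 + genotype" else "1"
  form <- stats::as.formula(paste("y ~", fixedPart, "+",
                                  paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) invokeRestart("muffleWarning"))
  vc <- lme4::VarCorr(fit)
  getVar <- function(nm) if (nm %in% names(vc)) as.numeric(vc[[nm]][1, 1]) else 0
  comps <- c(sigma_g2 = if (genotypeAs == "random") getVar("genotype") else NA_real_,
             sigma_ge2 = getVar("genotype:year"),
             sigma_year2 = getVar("year"),
             sigma_rep2 = getVar("yearRep"),
             sigma_e2 = stats::sigma(fit)^2)
  ebl <- numeric(0)
  if (genotypeAs == "fixed") {
    fe <- lme4::fixef(fit)
    ebl <- setNames(as.numeric(fe), sub("^genotype", "", names(fe)))
  }
  conv <- is.null(fit@optinfo$conv$lme4$code) ||
    identical(fit@optinfo$conv$lme4$code, 0L)
  new("StageOneFit", trait = trait, condition = condition, eblues = ebl,
      varComponents = comps,
      H2 = NA_real_, logLik = as.numeric(stats::logLik(fit)),
      converged = isTRUE(conv))
}

#' Broad-sense heritability on an entry-mean basis
#'
#' H2 = sigma_g2 / (sigma_g2 + sigma_ge2 / y + sigma_e2 / (y r)), where y
#' is the number of years and r the number of replicates per year; the
#' result is clamped to [0, 1].
#'
#' @param fit a \code{StageOneFit} produced with \code{genotypeAs = "random"}.
#' @param nYears,nReps design counts.
#' @return Heritability (scalar in [0, 1]).
#' @export
heritability <- function(fit, nYears, nReps) {
  stopifnot(is(fit, "StageOneFit"))
  vc <- fit@varComponents
  if (is.na(vc[["sigma_g2"]]))
    stopf("heritability needs a fit with genotypeAs = 'random'")
  num <- vc[["sigma_g2"]]
  den <- num + vc[["sigma_ge2"]] / nYears + vc[["sigma_e2"]] / (nYears * nReps)
  if (den <= 0) {
    warnf("all variance components are zero; heritability reported as 0")
    return(0)
  }
  min(max(num / den, 0), 1)
}

#' Summary statistics of a set of E-BLUEs
#'
#' Mean, minimum, maximum, standard error (sd / sqrt(n)) and coefficient
#' of variation (sd / |mean|) over genotypes. The absolute mean keeps the
#' CV meaningful for negative-mean index traits; a zero mean yields an
#' undefined (NA) CV with a warning.
#'
#' @param eblues named numeric vector of adjusted genotype means.
#' @return data.frame with columns mean, min, max, SE, CV.
#' @export
summarizeEblues <- function(eblues) {
  eblues <- eblues[is.finite(eblues)]
  if (length(eblues) < 2L) stopf("need at least 2 genotypes to summarize")
  m <- mean(eblues); s <- sd(eblues)
  cv <- if (m == 0) {
    warnf("mean is exactly 0; CV undefined")
    NA_real_
  } else s / abs(m)
  data.frame(mean = m, min = min(eblues), max = max(eblues),
             SE = s / sqrt(length(eblues)), CV = cv)
}

olsResiduals <- function(yv, xv, what) {
  common <- intersect(names(yv), names(xv))
  if (length(common) != length(yv) || length(common) != length(xv))
    stopf("%s requires the same genotype set for both traits", what)
  x <- xv[common]; y <- yv[common]
  if (sd(x) == 0) stopf("%s: zero variance in the regressor; slope undefined", what)
  f <- lm(y ~ x)
  setNames(stats::residuals(f), common)
}

#' Grain protein deviation
#'
#' Residuals of the ordinary least-squares regression of protein content
#' on grain yield over genotypes within a condition: genotypes with
#' positive GPD carry more protein than their yield level predicts.
#'
#' @param gpc named E-BLUE vector of grain protein content.
#' @param gy named E-BLUE vector of grain yield (same genotypes).
#' @return named vector of deviations (residuals).
#' @export
deriveGPD <- function(gpc, gy) olsResiduals(gpc, gy, "deriveGPD")

#' Grain yield deviation
#'
#' Mirror image of \code{\link{deriveGPD}}: residuals of grain yield
#' regressed on protein content.
#'
#' @param gy named E-BLUE vector of grain yield.
#' @param gpc named E-BLUE vector of grain protein content (same genotypes).
#' @return named vector of deviations (residuals).
#' @export
deriveGYD <- function(gy, gpc) olsResiduals(gy, gpc, "deriveGYD")

#' Fixed-effects ANOVA of the raw plot data across conditions
#'
#' Sequential (type I) analysis of variance with terms genotype, year,
#' condition, block (replicate within year x condition), genotype x year,
#' genotype x condition and genotype x year x condition, with significance
#' stars at < 0.001, < 0.01 and < 0.05. Terms that are aliased in an
#' incomplete design are dropped by the fit with a warning.
#'
#' @param plots plot-record data.frame across both conditions.
#' @param trait trait column to analyse.
#' @return data.frame with columns term, df, sumsq, meansq, Fvalue, p,
#'   stars.
#' @export
anovaRaw <- function(plots, trait) {
  checkPlots(plots, trait)
  d <- data.frame(y = plots[[trait]],
                  genotype = factor(plots$genotype),
                  year = factor(plots$year),
                  condition = factor(plots$condition),
                  block = interaction(plots$year, plots$condition,
                                      plots$replicate, drop = TRUE))
  d <- d[is.finite(d$y), , drop = FALSE]
  form <- y ~ genotype + year + condition + block + genotype:year +
    genotype:condition + genotype:year:condition
  fit <- aov(form, data = d)
  tab <- summary(fit)[[1]]
  term <- trimws(rownames(tab))
  full <- c("genotype", "year", "condition", "block", "genotype:year",
            "genotype:condition", "genotype:year:condition")
  dropped <- setdiff(full, term)
  if (length(dropped))
    warnf("aliased terms dropped from the ANOVA: %s", paste(dropped, collapse = ", "))
  p <- tab[["Pr(>F)"]]
  stars <- ifelse(is.na(p), "",
           ifelse(p < 0.001, "***",
           ifelse(p < 0.01, "**",
           ifelse(p < 0.05, "*", "ns"))))
  data.frame(term = term, df = tab$Df, sumsq = tab[["Sum Sq"]],
             meansq = tab[["Mean Sq"]], Fvalue = tab[["F value"]],
             p = p, stars = stars, row.names = NULL)
}
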