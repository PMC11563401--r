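## End-to-end orchestration: genotype QC and kinship construction,
## stage-one analysis with trait summaries and deviation indices,
## genetic-parameter estimation with secondary-trait selection, both
## cross-validation analyses, mean-separation reporting, and a checksum
## manifest. All randomness flows from one master seed through
## childSeed(), so a rerun is byte-identical.

#' Assemble a run configuration
#'
#' @param simulation a \code{SimConfig} describing the synthetic study to
#'   generate, or NULL when reading data from files.
#' @param genotypeFile,plotFile input paths (used when
#'   \code{simulation} is NULL): a delimited dosage matrix
#'   (\code{\link{readGenotypeMatrix}}) and a plot table
#'   (\code{\link{readPlots}}).
#' @param outDir output directory (created if absent).
#' @param mafMin,missingMax marker QC thresholds.
#' @param targetTrait trait predicted in the correlated-traits analysis.
#' @param excludeFromSelection traits never selected as secondaries
#'   (derivative indices of the target).
#' @param kSecondaries how many secondary traits to select (default 5).
#' @param models prediction models to run.
#' @param nFolds,nRepeats cross-validation plan.
#' @param masterSeed master seed; every stage derives its own stream.
#' @param gibbs,rf sampler/forest settings templates.
#' @return A validated list of class \code{"mtgpRunConfig"}.
#' @export
runConfig <- function(simulation = simConfig(), genotypeFile = NULL,
                      plotFile = NULL, outDir = tempfile("mtgp_run_"),
                      mafMin = 0.05, missingMax = 0.20,
                      targetTrait = "GY",
                      excludeFromSelection = c("GYD", "GPD"),
                      kSecondaries = 5L,
                      models = c("UV_GBLUP", "MV_GBLUP"),
                      nFolds = 5L, nRepeats = 10L, masterSeed = 1L,
                      gibbs = gibbsConfig(), rf = rfConfig()) {
  if (is.null(simulation) && (is.null(genotypeFile) || is.null(plotFile)))
    stopf("either a simulation config or both input files are required")
  cfg <- list(simulation = simulation, genotypeFile = genotypeFile,
              plotFile = plotFile, outDir = outDir, mafMin = mafMin,
              missingMax = missingMax, targetTrait = targetTrait,
              excludeFromSelection = excludeFromSelection,
              kSecondaries = as.integer(kSecondaries), models = models,
              nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats),
              masterSeed = as.integer(masterSeed), gibbs = gibbs, rf = rf)
  class(cfg) <- "mtgpRunConfig"
  cfg
}

writeTableHashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg2 <- cfg
  cfg2$outDir <- NULL # the hash identifies the analysis, not its location
  writeLines(deparse(cfg2), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the complete analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic generation or file
#' input), marker QC and kinship construction, per-trait/per-condition
#' stage-one fits with adjusted means, variance components, heritability
#' and summary statistics, protein/yield deviation indices, genomic
#' genetic correlations with the target trait and secondary-trait
#' selection, both cross-validation analyses over the requested models
#' and schemes, Duncan letter groupings and the cross-condition Fisher
#' comparison, and a checksum manifest of every artifact. Any stage
#' failure halts with the stage name; partial outputs are preserved.
#'
#' @param cfg a configuration from \code{\link{runConfig}}.
#' @param verbose print stage milestones (default TRUE).
#' @return (Invisibly) a list with the main in-memory results and the
#'   output paths.
#' @export
runFullAnalysis <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "mtgpRunConfig"))
  hash <- configHash(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  stage <- "input"
  res <- tryCatch({
    ## ---- input ----
    if (!is.null(cfg$simulation)) {
      say(stage, "simulating study (seed %d)", cfg$simulation@seed)
      study <- simulateTrial(cfg$simulation)
      gmRaw <- genotypeData(study)
      plots <- plotRecords(study)
      writeSimConfig(cfg$simulation, file.path(cfg$outDir, "sim_config.txt"))
    } else {
      say(stage, "reading %s and %s", cfg$genotypeFile, cfg$plotFile)
      gmRaw <- readGenotypeMatrix(cfg$genotypeFile)
      plots <- readPlots(cfg$plotFile)
      study <- NULL
    }
    traitCols <- setdiff(names(plots), c("genotype", "year", "condition", "replicate"))
    if (!cfg$targetTrait %in% traitCols)
      stopf("target trait '%s' not present in plot table (traits: %s)",
            cfg$targetTrait, paste(traitCols, collapse = ", "))
    conditions <- unique(plots$condition)

    ## ---- genotype QC and kinships ----
    stage <- "qc"
    gmF <- filterMarkers(gmRaw, cfg$mafMin, cfg$missingMax)
    gm <- imputeMean(recodePM1(gmF))
    K <- computeKernels(gm)
    say(stage, "markers: %d in, %d after QC", ncol(dosages(gmRaw)), ncol(dosages(gm)))
    writeGenotypeMatrix(gm, file.path(cfg$outDir, "genotypes_qc.tsv"))
    writeSquareMatrix(round(grm(K), 8), file.path(cfg$outDir, "grm.tsv"))

    ## ---- stage one ----
    stage <- "stage_one"
    nYears <- length(unique(plots$year))
    nReps <- length(unique(plots$replicate))
    ebluesList <- list(); statsRows <- list()
    for (cond in conditions) {
      em <- NULL
      for (trait in traitCols) {
        fitF <- fitStageOne(plots, trait, cond, genotypeAs = "fixed")
        fitR <- fitStageOne(plots, trait, cond, genotypeAs = "random")
        h2 <- heritability(fitR, nYears, nReps)
        e <- eblues(fitF)
        em <- if (is.null(em)) matrix(e, ncol = 1,
                                      dimnames = list(names(e), trait))
        else cbind(em, e[rownames(em)])
        colnames(em)[ncol(em)] <- trait
        s <- summarizeEblues(e)
        statsRows[[paste(trait, cond)]] <- data.frame(
          trait = trait, condition = cond, s, H2 = h2)
      }
      ## deviation indices when both protein and yield are present
      if (all(c("GY", "GPC") %in% colnames(em))) {
        em <- cbind(em,
                    GPD = deriveGPD(em[, "GPC"], em[, "GY"])[rownames(em)],
                    GYD = deriveGYD(em[, "GY"], em[, "GPC"])[rownames(em)])
        for (ix in c("GPD", "GYD"))
          statsRows[[paste(ix, cond)]] <- data.frame(
            trait = ix, condition = cond, summarizeEblues(em[, ix]),
            H2 = NA_real_)
      }
      ebluesList[[cond]] <- em
      writeTableHashed(data.frame(genotype = rownames(em), em,
                                  check.names = FALSE),
                       file.path(cfg$outDir, sprintf("eblues_%s.tsv", cond)),
                       hash)
    }
    traitStats <- do.call(rbind, statsRows); rownames(traitStats) <- NULL
    writeTableHashed(traitStats, file.path(cfg$outDir, "trait_summary.tsv"), hash)
    anovaTab <- anovaRaw(plots, cfg$targetTrait)
    writeTableHashed(anovaTab, file.path(cfg$outDir,
                     sprintf("anova_%s.tsv", cfg$targetTrait)), hash)
    say(stage, "stage-one fits done for %d traits x %d conditions",
        length(traitCols), length(conditions))

    ## ---- genetic parameters and secondary selection ----
    stage <- "genetic_params"
    rhoTables <- list(); secondaries <- list()
    for (cond in conditions) {
      em <- ebluesList[[cond]]
      others <- setdiff(colnames(em), cfg$targetTrait)
      rho <- vapply(others, function(tr) {
        gp <- estimateGeneticCovariance(em[, c(cfg$targetTrait, tr)], K)
        gp@rhoG
      }, numeric(1))
      rhoTables[[cond]] <- data.frame(condition = cond, trait = others,
                                      rhoG = unname(rho))
      secondaries[[cond]] <- selectTopCorrelated(
        rho, cfg$targetTrait, cfg$kSecondaries, cfg$excludeFromSelection)
      say(stage, "%s secondaries: %s", cond,
          paste(secondaries[[cond]], collapse = ", "))
    }
    writeTableHashed(do.call(rbind, rhoTables),
                     file.path(cfg$outDir, "genetic_correlations.tsv"), hash)

    ## ---- cross-validation ----
    stage <- "cv"
    plan <- makeFolds(rownames(dosages(gm)),
                      childSeed(cfg$masterSeed, "folds"),
                      cfg$nFolds, cfg$nRepeats)
    allRes <- list()
    ## analysis 1: same trait in all conditions jointly
    if (length(conditions) >= 2L) {
      ph1 <- do.call(cbind, lapply(conditions, function(cond) {
        m <- ebluesList[[cond]][, cfg$targetTrait, drop = FALSE]
        colnames(m) <- paste(cfg$targetTrait, cond, sep = "_")
        m
      }))
      for (cond in conditions) {
        tgt <- paste(cfg$targetTrait, cond, sep = "_")
        sec <- setdiff(colnames(ph1), tgt)
        specs <- list(
          schemeSpec("UV_CV1", "same_trait_two_conditions", tgt),
          schemeSpec("MV_CV1", "same_trait_two_conditions", tgt, sec),
          schemeSpec("MV_CV2", "same_trait_two_conditions", tgt, sec))
        for (sp in specs) {
          allRes[[length(allRes) + 1L]] <- runExperiment(
            cfg$models, sp, ph1, K, gm, plan,
            masterSeed = childSeed(cfg$masterSeed, "cv", "same_trait", cond),
            gibbsCfg = cfg$gibbs, rfCfg = cfg$rf)
        }
      }
    }
    ## analysis 2: target with its most correlated traits, per condition
    for (cond in conditions) {
      em <- ebluesList[[cond]]
      ph2 <- em[, c(cfg$targetTrait, secondaries[[cond]]), drop = FALSE]
      specs <- list(
        schemeSpec("UV_CV1", "target_with_secondaries", cfg$targetTrait),
        schemeSpec("MV_CV1", "target_with_secondaries", cfg$targetTrait,
                   secondaries[[cond]]),
        schemeSpec("MV_CV2", "target_with_secondaries", cfg$targetTrait,
                   secondaries[[cond]]))
      for (sp in specs) {
        r <- runExperiment(
          cfg$models, sp, ph2, K, gm, plan,
          masterSeed = childSeed(cfg$masterSeed, "cv", "secondaries", cond),
          gibbsCfg = cfg$gibbs, rfCfg = cfg$rf)
        if (nrow(r)) r$condition <- cond
        allRes[[length(allRes) + 1L]] <- r
      }
    }
    allRes <- allRes[vapply(allRes, nrow, integer(1)) > 0]
    cvLong <- do.call(rbind, lapply(allRes, function(d) {
      if (!"condition" %in% names(d)) d$condition <- NA_character_
      d
    }))
    writeTableHashed(cvLong, file.path(cfg$outDir, "cv_accuracies_long.tsv"), hash)

    ## ---- reporting ----
    stage <- "report"
    cvSummary <- summarizeCV(cvLong)
    ## Duncan letters within each target row across model x scheme cells
    letterRows <- list()
    for (tgt in unique(cvLong$target)) {
      d <- cvLong[cvLong$target == tgt, ]
      cells <- split(d$accuracy, paste(d$model, d$scheme, sep = ":"))
      cells <- lapply(cells, function(v) v[is.finite(v)])
      if (length(cells) >= 2L && length(unique(lengths(cells))) == 1L) {
        dt <- duncanTest(cells)
        letterRows[[tgt]] <- data.frame(target = tgt, dt)
      }
    }
    if (length(letterRows)) {
      writeTableHashed(do.call(rbind, letterRows),
                       file.path(cfg$outDir, "duncan_letters.tsv"), hash)
    }
    ## Fisher comparison of the univariate accuracy across conditions
    fisherRows <- list()
    uv <- cvSummary[cvSummary$model == "UV_GBLUP", ]
    if (length(conditions) >= 2L && nrow(uv) >= 2L) {
      tgts <- paste(cfg$targetTrait, conditions[1:2], sep = "_")
      if (all(tgts %in% uv$target)) {
        r1 <- uv$mean[uv$target == tgts[1]]
        r2 <- uv$mean[uv$target == tgts[2]]
        nPanel <- nrow(dosages(gm))
        fc <- fisherCompare(r1, nPanel, r2, nPanel)
        fisherRows[[1]] <- data.frame(target = cfg$targetTrait,
                                      cond1 = conditions[1], r1 = r1,
                                      cond2 = conditions[2], r2 = r2,
                                      z = fc$z, p = fc$p)
        writeTableHashed(fisherRows[[1]],
                         file.path(cfg$outDir, "fisher_conditions.tsv"), hash)
      }
    }
    writeTableHashed(cvSummary, file.path(cfg$outDir, "cv_summary.tsv"), hash)

    ## ---- manifest ----
    stage <- "manifest"
    files <- sort(setdiff(list.files(cfg$outDir), "manifest.tsv"))
    sums <- tools::md5sum(file.path(cfg$outDir, files))
    manifest <- data.frame(file = files, md5 = unname(sums),
                           config_hash = hash)
    write.table(manifest, file.path(cfg$outDir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    say("done", "all artifacts in %s", cfg$outDir)
    list(study = study, kinship = K, eblues = ebluesList,
         traitStats = traitStats, geneticCorrelations = rhoTables,
         secondaries = secondaries, cv = cvLong, cvSummary = cvSummary,
         outDir = cfg$outDir, configHash = hash)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}
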