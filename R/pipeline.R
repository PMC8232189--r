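#' Default pipeline configuration
#'
#' A nested list accepted by [runPipeline()]: a simulation preset (or input
#' file paths), QC thresholds, map parameters and scan options, all seeded
#' from one integer.  The default scales the simulated study down (2
#' chromosomes, 15 markers each, 60 genotypes, no scans) so the full
#' pipeline runs in seconds; set the fields to the full preset for a
#' production run.
#'
#' @param seed integer seed controlling all randomness.
#' @return config list.
#' @export
defaultStudyConfig <- function(seed = 1L) {
    list(
        seed = seed,
        simulate = list(nGenotypes = 60L, nMarkersPerChrom = 15L,
                        chromLength = 120, nChrom = 2L,
                        selection = "none", qtls = NULL, design = "rye"),
        input = list(genotypeCsv = NULL, phenotypeCsv = NULL),
        qc = list(maxMissing = 0.10),
        map = list(run = TRUE, rfMax = 0.35, lodMin = 6),
        scan = list(run = FALSE, traits = NULL, cofactors = "none",
                    alpha = 0.05, pcaShare = 0.995, epistasis = FALSE))
}

.validateConfig <- function(config) {
    a <- config$scan$alpha
    if (!is.numeric(a) || length(a) != 1L || a <= 0 || a > 1)
        stop("config error: scan$alpha must lie in (0, 1]")
    mm <- config$qc$maxMissing
    if (!is.numeric(mm) || mm < 0 || mm > 1)
        stop("config error: qc$maxMissing must lie in [0, 1]")
    for (p in unlist(config$input))
        if (!is.null(p) && !file.exists(p))
            stop("config error: input file does not exist: ", p)
    invisible(config)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> marker QC (missingness filter, redundancy
#' collapse, flank imputation, distortion and allele-frequency tracks,
#' multivalent screen) -> linkage map -> phenotype mixed models (variance
#' components, BLUEs, heritability) -> optional genome scans
#' (none/CM1/CM2 cofactors) and epistasis scan.  Every stage's output is
#' written under `outdir` (CSV/TSV/YAML only) and counted in the run
#' manifest; the whole run is deterministic under the config seed.  A
#' stage error aborts with the stage name, after writing the manifest
#' accumulated so far.
#'
#' @param config list as from [defaultStudyConfig()], or path to a YAML
#'   file with the same structure.
#' @param outdir output directory (created if needed).
#' @return the run manifest (list), invisibly written to
#'   `manifest.yaml`.
#' @export
runPipeline <- function(config = defaultStudyConfig(), outdir) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    .validateConfig(config)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(package = "ryeqtl",
                     version = as.character(utils::packageVersion("ryeqtl")),
                     seed = config$seed, started = format(Sys.time()),
                     stages = list())
    stageEnv <- new.env()
    finish <- function() {
        manifest$finished <- format(Sys.time())
        yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
        manifest
    }
    runStage <- function(name, fun) {
        res <- tryCatch(fun(), error = function(e) {
            manifest$stages[[name]] <<- list(status = "error",
                                             message = conditionMessage(e))
            finish()
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE)
        })
        manifest$stages[[name]] <<- res
        invisible(res)
    }
    set.seed(config$seed)

    runStage("input", function() {
        if (!is.null(config$input$genotypeCsv)) {
            abh <- readGenotypeCsv(config$input$genotypeCsv)
            pheno <- readPhenotypeCsv(config$input$phenotypeCsv)
            stageEnv$study <- new("SimulatedStudy", geno = abh, pheno = pheno,
                                  truth = list())
        } else {
            sim <- config$simulate
            genome <- genomeSpec(paste0(seq_len(sim$nChrom), "R"),
                                 rep(sim$chromLength, sim$nChrom),
                                 sim$nMarkersPerChrom)
            sel <- switch(sim$selection,
                          none = selectionSpec(),
                          rye = ryeSelection(genome),
                          sim$selection)
            des <- if (identical(sim$design, "rye")) ryeTrialDesign()
                   else sim$design
            qtls <- if (is.null(sim$qtls))
                qtlEffects(character(), character(), numeric(), numeric())
            else sim$qtls
            stageEnv$study <- simulateStudy(genome, sim$nGenotypes, sel,
                                            qtls, des, seed = config$seed)
            writeGenotypeCsv(genoData(stageEnv$study),
                             file.path(outdir, "genotypes.csv"))
            writePhenotypeCsv(phenoData(stageEnv$study),
                              file.path(outdir, "phenotypes.csv"))
            tr <- truthRecord(genoData(stageEnv$study))
            yaml::write_yaml(list(seed = config$seed,
                                  generation = tr$generation,
                                  nGenotypes = ncol(genoData(stageEnv$study)),
                                  nMarkers = nrow(genoData(stageEnv$study))),
                             file.path(outdir, "truth.yaml"))
        }
        list(status = "ok", genotypes = ncol(genoData(stageEnv$study)),
             markersIn = nrow(genoData(stageEnv$study)))
    })

    runStage("qc", function() {
        abh <- genoData(stageEnv$study)
        nIn <- nrow(abh)
        filtered <- filterMissing(abh, config$qc$maxMissing)
        nFiltered <- nrow(filtered)
        gone <- setdiff(rownames(abh), rownames(filtered))
        dropped <- data.frame(
            marker = gone,
            rule = rep(sprintf("missing fraction > %g", config$qc$maxMissing),
                       length(gone)))
        cr <- collapseRedundant(filtered)
        abh <- cr$abh
        nUnique <- nrow(abh)
        red <- cr$groups[!cr$groups$marker %in% rownames(abh), , drop = FALSE]
        if (nrow(red))
            dropped <- rbind(dropped, data.frame(
                marker = red$marker,
                rule = paste("redundant with", red$representative)))
        write.table(dropped, file.path(outdir, "qc_dropped.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        if (anyNA(calls(abh))) abh <- imputeByFlanks(abh)
        stageEnv$abh <- abh
        dist <- distortionScan(abh)
        write.table(dist, file.path(outdir, "distortion.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        freq <- alleleFrequencyProfile(abh)
        write.table(freq, file.path(outdir, "allele_freq.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        scr <- multivalentScreen(abh)
        write.table(scr$flags, file.path(outdir, "multivalent_flags.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        list(status = "ok", markersIn = nIn, markersAfterMissing = nFiltered,
             markersUnique = nUnique, markersDropped = nrow(dropped),
             distortedAt5pct = sum(dist$sig5),
             multivalentFlags = nrow(scr$flags))
    })

    if (isTRUE(config$map$run)) runStage("map", function() {
        map <- buildLinkageMap(stageEnv$abh, config$map$rfMax,
                               config$map$lodMin)
        stageEnv$map <- map
        write.table(map, file.path(outdir, "map.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        list(status = "ok", markersIn = nrow(stageEnv$abh),
             groups = length(unique(map$group)))
    })

    runStage("pheno", function() {
        pheno <- phenoData(stageEnv$study)
        traits <- unique(pheno$trait)
        stageEnv$blues <- list()
        res <- list()
        for (tr in traits) {
            vc <- fitUnivariate(pheno, tr, "random")
            bl <- fitUnivariate(pheno, tr, "fixed")
            h2 <- heritability(varComp(vc)[["genotype"]], avVD(bl))
            comp <- data.frame(component = names(varComp(vc)),
                               estimate = unname(varComp(vc)),
                               se = unname(varCompSE(vc)))
            write.table(comp,
                        file.path(outdir, paste0("varcomp_", tr, ".tsv")),
                        sep = "\t", row.names = FALSE, quote = FALSE)
            write.table(blues(bl),
                        file.path(outdir, paste0("blues_", tr, ".tsv")),
                        sep = "\t", row.names = FALSE, quote = FALSE)
            stageEnv$blues[[tr]] <- bl
            res[[tr]] <- list(H2 = round(h2, 4), avVD = round(avVD(bl), 4))
        }
        c(list(status = "ok"), res)
    })

    if (isTRUE(config$scan$run)) runStage("scan", function() {
        pheno <- phenoData(stageEnv$study)
        abh <- stageEnv$abh
        traits <- config$scan$traits
        if (is.null(traits)) traits <- unique(pheno$trait)
        thr <- simpleMThreshold(abh, config$scan$alpha,
                                config$scan$pcaShare)
        counts <- list(status = "ok", qEff = thr$qEff,
                       threshold = thr$threshold)
        for (tr in traits) {
            sc <- scanGenome(pheno, abh, tr)
            cof <- character()
            if (config$scan$cofactors == "cm1")
                cof <- selectCofactorsCM1(sc, thr$threshold)
            if (config$scan$cofactors == "cm2")
                cof <- selectCofactorsCM2(stageEnv$blues[[tr]], abh)
            if (length(cof))
                sc <- scanGenome(pheno, abh, tr, cofactors = cof,
                                 dropSameChromCofactors =
                                     config$scan$cofactors == "cm1")
            sc$significant <- sc$pCdD < thr$threshold
            write.table(sc, file.path(outdir, paste0("scan_", tr, ".tsv")),
                        sep = "\t", row.names = FALSE, quote = FALSE)
            counts[[tr]] <- list(markersTested = nrow(sc),
                                 significant = sum(sc$significant),
                                 cofactors = length(cof))
            if (isTRUE(config$scan$epistasis)) {
                sig <- sc$marker[sc$significant]
                if (length(sig) >= 2L) {
                    prs <- t(combn(sig, 2L))
                    ep <- epistasisScan(pheno, abh, tr, prs, thr$qEff,
                                        config$scan$alpha)
                    write.table(ep, file.path(outdir,
                                              paste0("epistasis_", tr, ".tsv")),
                                sep = "\t", row.names = FALSE, quote = FALSE)
                    counts[[tr]]$epistasisPairs <- nrow(prs)
                }
            }
        }
        counts
    })

    runStage("report", function() {
        rep_ <- incompatibilityReport()
        yaml::write_yaml(rep_, file.path(outdir, "ratios.yaml"))
        list(status = "ok")
    })
    finish()
}
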