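#' @include AllClasses.R synthetic.R gating.R derivation.R scoring.R tcr.R
#' @include survival.R refine.R cohort.R io.R
NULL

# One global seed fans out to per-stage seeds so stages can be re-run in
# isolation with the seed logged in the report.
.stage_seed <- function(seed, stage) {
    (as.integer(seed) * 1009L + stage) %% 2147483647L
}

#' Default pipeline configuration
#'
#' Returns the nested configuration list understood by
#' \code{\link{runPipeline}}: stage toggles, per-stage designs/configs, a
#' global seed and (optionally) input paths used instead of simulation.
#' Any sub-list can be overridden by the \code{...} arguments.
#'
#' @param seed global seed fanned out to per-stage seeds.
#' @param ... named overrides merged over the defaults (one level deep).
#' @return configuration list.
#' @export
pipelineConfig <- function(seed = 1, ...) {
    cfg <- list(
        seed = seed,
        stages = list(simulate = TRUE, filter = TRUE, derive = TRUE,
                      tcr = TRUE, score = TRUE, survival = TRUE,
                      refine = TRUE, response = TRUE),
        sc = list(nGenes = 1000, nCells = 600, nStates = 7,
                  reactiveState = 1, nSignatureGenes = 40, markerShift = 2,
                  dropoutRate = 0.3, baseMean = 2, noiseSd = 1,
                  nPatients = 10),
        tcrDesign = list(clonalEnrichment = 5, maxCloneSize = 50,
                         nClonotypes = 400),
        cohort = list(nSamples = 200, latentEffect = -0.7,
                      baselineHazard = 0.1, censorRate = 0.05,
                      signatureLoading = 1, responseLogitSlope = 1.5,
                      nBackgroundGenes = 200),
        derive = list(k = 20, alphaFdr = 0.05),
        filter = list(profile = "smartseq2_bulklike"),
        scoring = list(method = "kcdf_ks", kernel = "gaussian"),
        clonality = list(clonalMinSize = 3, depth = "min", reps = 1000),
        evaluation = list(ties = "efron"),
        inputs = list())
    over <- list(...)
    for (nm in names(over)) {
        if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
            cfg[[nm]][names(over[[nm]])] <- over[[nm]]
        else cfg[[nm]] <- over[[nm]]
    }
    cfg
}

.provenance_header <- function(seed) {
    sprintf("TRSig %s; seed=%s",
            as.character(utils::packageVersion("TRSig")), seed)
}

#' Run the full tumor-reactivity workflow
#'
#' Executes the enabled stages in dependency order -- simulate (or load)
#' single-cell data, filter, derive the signature, build clonotypes and
#' rarefied diversity, simulate (or load) a bulk cohort, score it, evaluate
#' survival (median split, log-rank, Cox, C-index, time-dependent AUC, RMST
#' ratio), refine the signature by stepwise AIC, and score a response
#' cohort -- and aggregates a machine-readable report.  Every artifact is
#' written with a provenance header (package version and seed); rerunning
#' with the same configuration is byte-identical.  A stage failure aborts
#' with the failing stage named.
#'
#' When \code{cfg$inputs} provides paths (\code{expr}, \code{annotation},
#' \code{tcr}, \code{survival} ...), those are loaded instead of simulating;
#' referenced paths are validated before any stage runs.
#'
#' @param cfg configuration list from \code{\link{pipelineConfig}}, or the
#'   path of a YAML file holding one.
#' @param outDir optional output directory for artifacts (created if
#'   needed); when NULL nothing is written.
#' @return the report, invisibly also written to
#'   \code{file.path(outDir, "report.json")} when \code{outDir} is given.
#' @examples
#' cfg <- pipelineConfig(seed = 7,
#'                       sc = list(nGenes = 200, nCells = 150),
#'                       cohort = list(nSamples = 60),
#'                       clonality = list(reps = 50),
#'                       stages = list(refine = FALSE))
#' rep <- runPipeline(cfg)
#' rep$signature$genes[1:5]
#' @export
runPipeline <- function(cfg = pipelineConfig(), outDir = NULL) {
    if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
    base <- pipelineConfig(seed = cfg$seed %||% 1)
    for (nm in names(cfg))
        if (is.list(cfg[[nm]]) && is.list(base[[nm]]))
            base[[nm]][names(cfg[[nm]])] <- cfg[[nm]] else
            base[[nm]] <- cfg[[nm]]
    cfg <- base
    # validate referenced inputs up front
    for (nm in names(cfg$inputs)) {
        path <- cfg$inputs[[nm]]
        .stop_if(!file.exists(path),
                 "configured input '", nm, "' does not exist: ", path)
    }
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    seed <- cfg$seed
    hdr <- .provenance_header(seed)
    report <- list(package = "TRSig",
                   version = as.character(utils::packageVersion("TRSig")),
                   seed = seed, config = cfg)
    stage <- function(name, enabled, fun) {
        if (!isTRUE(enabled)) return(NULL)
        tryCatch(fun(), error = function(e) {
            if (!is.null(outDir))
                writeLines(paste("FAILED at stage:", name, "-",
                                 conditionMessage(e)),
                           file.path(outDir, "FAILED"))
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE)
        })
    }

    ## -- single-cell data -----------------------------------------------
    sc <- stage("simulate_sc", TRUE, function() {
        if (!is.null(cfg$inputs$expr)) {
            expr <- readExprMatrix(cfg$inputs$expr, scale = "log2")
            ann <- utils::read.table(cfg$inputs$annotation, header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE)
            metadata(expr)$reactiveState <- cfg$derive$target
            colData(expr)$state <- ann$state[match(colnames(expr),
                                                   ann$cell_id)]
            colData(expr)$cell_id <- colnames(expr)
            colData(expr)$patient <-
                if ("patient" %in% names(ann))
                    ann$patient[match(colnames(expr), ann$cell_id)]
                else "P01"
            expr
        } else {
            simulateScDataset(do.call(scDesign, c(
                cfg$sc, list(seed = .stage_seed(seed, 1L)))))
        }
    })
    filtered <- stage("filter", cfg$stages$filter, function() {
        filterGenesCells(sc, do.call(filterProfile,
                                     list(name = cfg$filter$profile)))
    }) %||% sc

    ## -- signature derivation -------------------------------------------
    signature <- stage("derive", cfg$stages$derive, function() {
        target <- cfg$derive$target %||% metadata(sc)$reactiveState
        sig <- deriveTRS(filtered, target = target, k = cfg$derive$k,
                         alphaFdr = cfg$derive$alphaFdr)
        if (!is.null(outDir))
            writeGMT(sig, file.path(outDir, "signature.gmt"),
                     description = hdr)
        sig
    })
    .stop_if(is.null(signature),
             "the derive stage is required by all downstream stages")
    planted <- metadata(sc)$plantedGenes
    report$signature <- list(
        genes = sigGenes(signature), auc = unname(sigAUC(signature)),
        k = signature@k,
        planted_overlap = if (!is.null(planted))
            length(intersect(sigGenes(signature), planted)) else NA)

    ## -- TCR clonality ---------------------------------------------------
    report$clonality <- stage("tcr", cfg$stages$tcr, function() {
        ct <- if (!is.null(cfg$inputs$tcr)) {
            classifyClonality(
                buildClonotypes(readClonotypeRecords(cfg$inputs$tcr)),
                do.call(clonalityConfig, cfg$clonality))
        } else {
            simulateTcrTable(sc, do.call(tcrDesign, c(
                cfg$tcrDesign, list(seed = .stage_seed(seed, 2L)))))
        }
        ccfg <- do.call(clonalityConfig, c(
            cfg$clonality, list(seed = .stage_seed(seed, 3L))))
        ct <- classifyClonality(ct, ccfg)
        ent <- rarefiedEntropy(ct, ccfg)
        d <- clonotypeData(ct)
        state <- colData(sc)$state[match(d$cell_id, colData(sc)$cell_id)]
        reactive <- metadata(sc)$reactiveState
        frac_clonal <- function(sel)
            if (any(sel)) mean(d$clonality[sel] == "clonal") else NA_real_
        if (!is.null(outDir))
            utils::write.table(d, file.path(outDir, "clonotypes.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        list(classes = as.list(table(d$clonality)),
             clonal_fraction_reactive = frac_clonal(state == reactive),
             clonal_fraction_other = frac_clonal(state != reactive),
             entropy = ent[, c("sample_id", "n_cells", "mean_entropy",
                               "sd_entropy")],
             depth = attr(ent, "depth"))
    })

    ## -- bulk cohort, scoring, survival ----------------------------------
    cohort <- stage("cohort", cfg$stages$score || cfg$stages$survival,
                    function() {
        if (!is.null(cfg$inputs$bulk_expr)) {
            list(expr = readExprMatrix(cfg$inputs$bulk_expr, scale = "log2"),
                 survival = readSurvivalTable(cfg$inputs$survival),
                 latent = NULL)
        } else {
            simulateBulkCohort(do.call(cohortDesign, c(
                cfg$cohort, list(seed = .stage_seed(seed, 4L)))), signature)
        }
    })
    scoresv <- stage("score", cfg$stages$score, function() {
        sv <- scoreSamples(cohort$expr, signature,
                           do.call(scoringConfig, cfg$scoring))
        if (!is.null(outDir))
            writeScores(sv, file.path(outDir, "scores.tsv"), header = hdr)
        sv
    })
    report$scores <- if (!is.null(scoresv)) list(
        method = scoreMethod(scoresv),
        mean = mean(scores(scoresv)), sd = stats::sd(scores(scoresv)),
        latent_spearman = if (!is.null(cohort$latent))
            spearmanAssoc(scores(scoresv), cohort$latent)$rho else NA)

    report$survival <- stage("survival", cfg$stages$survival &&
                                 !is.null(scoresv), function() {
        s <- scores(scoresv)
        surv <- cohort$survival[match(names(s), cohort$survival$sample_id), ]
        grp <- stratifyMedian(s)
        lr <- logrankTest(surv$time, surv$event, grp)
        risk <- linearRiskScore(scoresv, negate = TRUE)
        cox <- coxFit(risk, surv$time, surv$event,
                      do.call(evalConfig, cfg$evaluation))
        tstar <- cfg$evaluation$tdaucTime %||% stats::median(surv$time)
        list(logrank_p = lr$p_value, logrank_chisq = lr$statistic,
             group_sizes = as.list(table(grp)),
             cox = list(beta = unname(coef(cox)),
                        hr = unname(hazardRatio(cox)),
                        se = unname(cox@se), aic = cox@aic),
             cindex = concordanceIndex(risk, surv$time, surv$event),
             td_auc = timeDependentAUC(risk, surv$time, surv$event, tstar),
             td_auc_time = tstar,
             rmst = {
                 r <- rmstRatio(surv$time, surv$event, grp,
                                tau = cfg$evaluation$rmstTau)
                 list(ratio = r$ratio, order = r$ratio_order, tau = r$tau)
             })
    })

    report$refinement <- stage("refine", cfg$stages$refine &&
                                   !is.null(cohort), function() {
        res <- refineSignature(cohort$expr, signature, cohort$survival,
                               do.call(scoringConfig, cfg$scoring),
                               do.call(evalConfig, cfg$evaluation))
        if (!is.null(outDir))
            utils::write.table(res$trace,
                               file.path(outDir, "refinement_trace.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        list(n_genes = length(res$signature),
             removed = res$trace$gene_removed,
             aic_trace = c(if (nrow(res$trace)) res$trace$aic_before[1],
                           res$trace$aic_after))
    })

    report$response <- stage("response", cfg$stages$response, function() {
        rc <- if (!is.null(cfg$inputs$response_expr)) {
            list(expr = readExprMatrix(cfg$inputs$response_expr,
                                       scale = "log2"),
                 response = utils::read.table(cfg$inputs$response,
                                              header = TRUE, sep = "\t"))
        } else {
            simulateResponseCohort(do.call(cohortDesign, c(
                cfg$cohort, list(seed = .stage_seed(seed, 5L)))), signature)
        }
        sv <- scoreSamples(rc$expr, signature,
                           do.call(scoringConfig, cfg$scoring))
        resp <- rc$response$responder[match(names(scores(sv)),
                                            rc$response$sample_id)]
        ra <- responseAUC(sv, resp)
        list(auc = ra$auc, p_value = ra$p_value,
             n_responder = ra$n_responder,
             n_nonresponder = ra$n_nonresponder)
    })

    if (!is.null(outDir)) {
        rep_out <- report
        rep_out$clonality$entropy <- NULL
        jsonlite::write_json(rep_out, file.path(outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             force = TRUE)
    }
    report
}
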