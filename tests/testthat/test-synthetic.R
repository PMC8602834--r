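test_that("single-cell generator honors shape, truth exposure and seeding", {
  d <- scDesign(nGenes = 500, nCells = 600, nStates = 4,
                nSignatureGenes = 40, seed = 7)
  sc <- simulateScDataset(d)
  expect_identical(dim(sc), c(500L, 600L))
  expect_identical(exprScale(sc), "log2")
  expect_length(metadata(sc)$plantedGenes, 40)
  expect_true(all(metadata(sc)$plantedGenes %in% rownames(sc)))
  ann <- colData(sc)
  expect_identical(nrow(ann), 600L)
  expect_false(anyNA(ann$state))
  expect_false(anyNA(ann$patient))
  # seeding contract
  sc2 <- simulateScDataset(d)
  expect_identical(exprValues(sc), exprValues(sc2))
  sc3 <- simulateScDataset(scDesign(nGenes = 500, nCells = 600, nStates = 4,
                                    nSignatureGenes = 40, seed = 8))
  expect_false(identical(exprValues(sc), exprValues(sc3)))
})

test_that("planted genes really shift only in the reactive state", {
  sc <- simulateScDataset(scDesign(nGenes = 200, nCells = 400, nStates = 4,
                                   nSignatureGenes = 20, markerShift = 3,
                                   dropoutRate = 0, seed = 2))
  ann <- colData(sc)
  reactive <- metadata(sc)$reactiveState
  planted <- metadata(sc)$plantedGenes
  m <- exprValues(sc)
  in_r <- ann$state == reactive
  shift_planted <- rowMeans(m[planted, in_r]) - rowMeans(m[planted, !in_r])
  bg <- setdiff(rownames(m), planted)
  shift_bg <- rowMeans(m[bg, in_r]) - rowMeans(m[bg, !in_r])
  expect_gt(mean(shift_planted), 2.5)
  expect_lt(max(abs(mean(shift_bg))), 0.5)
})

test_that("markerShift = 0 leaves planted genes indistinguishable", {
  sc <- simulateScDataset(scDesign(nGenes = 400, nCells = 600,
                                   nSignatureGenes = 40, markerShift = 0,
                                   seed = 5))
  mk <- wilcoxonMarkers(sc, target = metadata(sc)$reactiveState,
                        alternative = "two.sided")
  planted_fdr <- mk$fdr[mk$gene %in% metadata(sc)$plantedGenes]
  expect_gte(mean(planted_fdr >= 0.05), 0.95)
})

test_that("invalid designs report the offending field", {
  expect_error(scDesign(nSignatureGenes = 1000, nGenes = 500),
               "nSignatureGenes")
  expect_error(scDesign(dropoutRate = 1), "dropoutRate")
  expect_error(scDesign(reactiveState = 9, nStates = 4), "reactiveState")
  expect_error(tcrDesign(clonalEnrichment = 0.5), "clonalEnrichment")
  expect_error(cohortDesign(baselineHazard = 0), "baselineHazard")
  expect_error(cohortDesign(nSamples = 5), "nSamples")
})

make_annotation <- function(n_cells = 200, seed = 1) {
  set.seed(seed)
  data.frame(cell_id = sprintf("c%03d", seq_len(n_cells)),
             state = sample(c("S1", "S2"), n_cells, replace = TRUE),
             patient = sample(c("P1", "P2", "P3"), n_cells, replace = TRUE))
}

test_that("clonal enrichment contract: null is symmetric, strong is strict", {
  ann <- make_annotation()
  mean_size_by_state <- function(ct) {
    d <- clonotypeData(ct)
    st <- ann$state[match(d$cell_id, ann$cell_id)]
    tapply(d$clone_size, st == "S1", mean)
  }
  null_r <- null_o <- enr_strict <- logical(20)
  null_sizes <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    ct0 <- simulateTcrTable(ann, tcrDesign(clonalEnrichment = 1, seed = s),
                            reactiveState = "S1")
    m0 <- mean_size_by_state(ct0)
    null_sizes[s, ] <- c(m0[["TRUE"]], m0[["FALSE"]])
    ct10 <- simulateTcrTable(ann, tcrDesign(clonalEnrichment = 10, seed = s),
                             reactiveState = "S1")
    m10 <- mean_size_by_state(ct10)
    enr_strict[s] <- m10[["TRUE"]] > m10[["FALSE"]]
  }
  # null: averaged over seeds, reactive vs non-reactive differ by < 10 %
  expect_lt(abs(mean(null_sizes[, 1]) / mean(null_sizes[, 2]) - 1), 0.1)
  expect_true(all(enr_strict))
})

test_that("saturated clonotype space yields (near-)all singletons", {
  ann <- make_annotation(100)
  ct <- simulateTcrTable(ann, tcrDesign(clonalEnrichment = 1,
                                        nClonotypes = 5000, seed = 3),
                         reactiveState = "S1")
  expect_gte(mean(clonotypeData(ct)$clone_size == 1), 0.9)
})

test_that("bulk cohort generator: censoring bookkeeping and null Cox type-I", {
  sig <- GeneSignature(paste0("SIG", 1:5))
  coh <- simulateBulkCohort(cohortDesign(nSamples = 50, censorRate = 0,
                                         seed = 4), sig)
  expect_true(all(coh$survival$event == 1))
  expect_identical(dim(exprValues(coh$expr)), c(205L, 50L))
  # under latentEffect = 0 the Wald interval covers 0 in >= 90 % of reps
  covered <- logical(50)
  for (s in 1:50) {
    c0 <- simulateBulkCohort(cohortDesign(nSamples = 100, latentEffect = 0,
                                          seed = s), sig)
    f <- coxFit(c0$latent, c0$survival$time, c0$survival$event)
    covered[s] <- abs(coef(f)) < 2 * f@se
  }
  expect_gte(mean(covered), 0.9)
})

test_that("response generator: null balance and steep-slope limit", {
  sig <- GeneSignature(paste0("SIG", 1:5))
  r0 <- simulateResponseCohort(cohortDesign(nSamples = 400,
                                            responseLogitSlope = 0,
                                            seed = 6), sig)
  frac <- mean(r0$response$responder)
  expect_lt(abs(frac - 0.5), 1.96 * sqrt(0.25 / 400) + 1e-9)
  # steep-slope limit: with slope s the exact expected agreement with
  # indicator(u > 0) is 1 - 2 E[plogis(-s|u|)] -- about 98.9 % at s = 50
  # and 99.9 % at s = 500
  r50 <- simulateResponseCohort(cohortDesign(nSamples = 400,
                                             responseLogitSlope = 50,
                                             seed = 6), sig)
  agree <- mean(r50$response$responder == as.integer(r50$latent > 0))
  expect_gte(agree, 0.97)
  r500 <- simulateResponseCohort(cohortDesign(nSamples = 400,
                                              responseLogitSlope = 500,
                                              seed = 6), sig)
  agree500 <- mean(r500$response$responder == as.integer(r500$latent > 0))
  expect_gte(agree500, 0.99)
})

test_that("signature-gene expression tracks the latent score", {
  sig <- GeneSignature(paste0("SIG", 1:10))
  coh <- simulateBulkCohort(cohortDesign(nSamples = 200, seed = 8), sig)
  m <- exprValues(coh$expr)
  sig_mean <- colMeans(m[sigGenes(sig), ])
  expect_gt(cor(sig_mean, coh$latent), 0.7)
  bg_mean <- colMeans(m[setdiff(rownames(m), sigGenes(sig)), ])
  expect_lt(abs(cor(bg_mean, coh$latent)), 0.3)
})
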