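rand_expr <- function(p, n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(p * n, 5, 2), p, n,
         dimnames = list(sprintf("g%03d", seq_len(p)),
                         sprintf("s%03d", seq_len(n))))
}

test_that("kernel CDF statistic matches its literal transcription", {
  m <- rand_expr(4, 5, seed = 10)
  expect_equal(kernelCdfStat(m), oracle_kcdf(m, "gaussian"),
               tolerance = 1e-10)
  cm <- matrix(rpois(20, 4), 4, 5, dimnames = dimnames(m))
  expect_equal(kernelCdfStat(cm, "poisson", scale = "counts"),
               oracle_kcdf(cm, "poisson"), tolerance = 1e-10)
})

test_that("kernel CDF conventions: constant rows, scale guard, sample floor", {
  m <- rand_expr(3, 6)
  m[2, ] <- 7
  z <- kernelCdfStat(m)
  expect_true(all(z[2, ] == 0.5))
  expect_error(kernelCdfStat(m[, 1:2]), "3 samples")
  expect_error(kernelCdfStat(m, "poisson"), "scale")
  neg <- m - 10
  expect_error(kernelCdfStat(neg, "poisson", scale = "counts"), "integer")
})

test_that("per-gene location shifts leave kernel ranks and scores unchanged", {
  m <- rand_expr(30, 12, seed = 11)
  z1 <- kernelCdfStat(m)
  m2 <- m
  m2[5, ] <- m2[5, ] + 100
  z2 <- kernelCdfStat(m2)
  expect_equal(z1[5, ], z2[5, ], tolerance = 1e-12)
  sig <- rownames(m)[c(3, 5, 9)]
  s1 <- scores(scoreSamples(m, sig, scoringConfig()))
  s2 <- scores(scoreSamples(m2, sig, scoringConfig()))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("kcdf KS walk equals the step-by-step oracle in both es modes", {
  m <- rand_expr(25, 8, seed = 12)
  sig <- rownames(m)[c(2, 7, 11, 20)]
  in_set <- rownames(m) %in% sig
  z <- kernelCdfStat(m)
  for (mode in c("max_diff", "max_abs")) {
    sv <- scoreSamples(m, sig, scoringConfig(esMode = mode))
    ref <- apply(z, 2, oracle_kcdf_walk, in_set = in_set, tau = 1,
                 es_mode = mode)
    expect_equal(unname(scores(sv)), unname(ref), tolerance = 1e-10)
  }
})

test_that("rank-weighted KS walk matches the hand walk and normalizes", {
  m <- rand_expr(6, 4, seed = 13)
  sig <- rownames(m)[c(2, 5)]
  in_set <- rownames(m) %in% sig
  sv <- scoreSamples(m, sig, scoringConfig(method = "rank_weighted_ks",
                                           rwksNormalize = FALSE))
  ref <- apply(m, 2, oracle_rwks_walk, in_set = in_set, alpha = 0.25)
  expect_equal(unname(scores(sv)), unname(ref), tolerance = 1e-10)
  svn <- scores(scoreSamples(m, sig,
                             scoringConfig(method = "rank_weighted_ks")))
  expect_equal(unname(svn), unname(ref / (max(ref) - min(ref))),
               tolerance = 1e-10)
  expect_error(scoreSamples(m, rownames(m),
                            scoringConfig(method = "rank_weighted_ks")),
               "universe")
})

test_that("per-sample monotone transforms leave the rank walk unchanged", {
  m <- rand_expr(40, 6, seed = 14)
  sig <- rownames(m)[1:8]
  cfg <- scoringConfig(method = "rank_weighted_ks", rwksNormalize = FALSE)
  s1 <- scores(scoreSamples(m, sig, cfg))
  m2 <- m
  for (j in seq_len(ncol(m))) m2[, j] <- exp(m2[, j] / (j + 1)) + j
  s2 <- scores(scoreSamples(m2, sig, cfg))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("combined z collapses, scales with sqrt(k), and centers", {
  m <- rand_expr(10, 15, seed = 15)
  cfg <- scoringConfig(method = "combined_z")
  g <- "g001"
  s1 <- scores(scoreSamples(m, g, cfg))
  z <- (m[g, ] - mean(m[g, ])) / sd(m[g, ])
  expect_equal(unname(s1), unname(z), tolerance = 1e-12)
  # duplicated identical gene doubles the sum but normalizes by sqrt(2)
  m2 <- rbind(m, dup = m[g, ])
  s2 <- scores(scoreSamples(m2, c(g, "dup"), cfg))
  expect_equal(unname(s2), unname(sqrt(2) * z), tolerance = 1e-12)
})

test_that("singular-vector scores are orientation-stable and sign-coherent", {
  set.seed(16)
  u <- rnorm(30)
  m <- rand_expr(12, 30, seed = 16)
  sig <- rownames(m)[1:5]
  m[sig, ] <- m[sig, ] + matrix(2 * u, 5, 30, byrow = TRUE)
  sv <- scores(scoreSamples(m, sig,
                            scoringConfig(method = "first_singular_vector")))
  expect_gt(cor(sv, u), 0.5)
  raw <- scores(scoreSamples(m, sig,
                             scoringConfig(method = "first_singular_vector",
                                           plageOrient = FALSE)))
  expect_true(isTRUE(all.equal(sv, raw, tolerance = 1e-10)) ||
                isTRUE(all.equal(sv, -raw, tolerance = 1e-10)))
})

test_that("mean scorer and missing-gene handling behave as declared", {
  m <- rand_expr(8, 5, seed = 17)
  sv <- scores(scoreSamples(m, c("g001", "g002", "ABSENT"),
                            scoringConfig(method = "mean")))
  expect_equal(unname(sv), unname(colMeans(m[c("g001", "g002"), ])),
               tolerance = 1e-12)
  expect_error(scoreSamples(m, c("NOPE", "NADA"), scoringConfig()),
               "NOPE")
})

test_that("recovery score reproduces the enumerated step curve", {
  # p = 100, T = 5, signature genes at ranks 1 and 3
  p <- 100
  x <- seq(p, 1)               # expression = reverse rank
  m <- toy_expr(x, genes = sprintf("g%03d", 1:p), obs = "cell1")
  sig <- c("g001", "g003")
  sv <- scoreCellsRecovery(m, sig,
                           scoringConfig(method = "ranking_recovery",
                                         tieMethod = "first"))
  expect_equal(unname(scores(sv)),
               oracle_recovery(c(1, 3), k = 2, p = p, top_fraction = 0.05),
               tolerance = 1e-12)
  # maximal and null recovery
  sv_top <- scoreCellsRecovery(m, c("g001", "g002"),
                               scoringConfig(method = "ranking_recovery",
                                             tieMethod = "first"))
  expect_equal(unname(scores(sv_top)), 1)
  sv_none <- scoreCellsRecovery(m, c("g099", "g100"),
                                scoringConfig(method = "ranking_recovery",
                                              tieMethod = "first"))
  expect_equal(unname(scores(sv_none)), 0)
  expect_warning(
    scoreCellsRecovery(m, sprintf("g%03d", 1:10),
                       scoringConfig(method = "ranking_recovery",
                                     recoveryTopFraction = 0.05)),
    "cannot reach 1")
})

test_that("scores permute with the samples and scorers track a latent truth", {
  sig <- GeneSignature(paste0("SIG", 1:10))
  coh <- simulateBulkCohort(cohortDesign(nSamples = 200, seed = 18), sig)
  m <- exprValues(coh$expr)
  perm <- sample(ncol(m))
  for (method in c("kcdf_ks", "rank_weighted_ks", "combined_z",
                   "first_singular_vector", "mean")) {
    cfg <- scoringConfig(method = method)
    s <- scores(scoreSamples(m, sig, cfg))
    sp <- scores(scoreSamples(m[, perm], sig, cfg))
    expect_equal(sp, s[colnames(m)[perm]], tolerance = 1e-9,
                 info = method)
    rho <- spearmanAssoc(s, coh$latent)$rho
    expect_gte(rho, 0.6)
  }
})
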