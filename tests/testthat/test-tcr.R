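rec <- function(alpha, beta, sample = "s1") {
  data.frame(cell_id = sprintf("c%02d", seq_along(alpha)),
             sample_id = sample, alpha = alpha, beta = beta,
             stringsAsFactors = FALSE)
}

test_that("clonotypes are exact chain pairs with consistent sizes", {
  ct <- buildClonotypes(rec(c("a1", "a1", "a1", "a1"),
                            c("b1", "b1", "b1", "b2")))
  sz <- sort(unname(cloneSizes(ct)), decreasing = TRUE)
  expect_identical(sz, c(3L, 1L))
  expect_identical(length(cloneSizes(ct)), 2L)
  # same alpha, different beta -> distinct clonotypes
  ct2 <- buildClonotypes(rec(c("a1", "a1"), c("b1", "b2")))
  expect_identical(length(cloneSizes(ct2)), 2L)
})

test_that("per-sample scope counts clone sizes locally", {
  r <- rbind(rec(c("a1", "a1"), c("b1", "b1"), sample = "s1"),
             rec(c("a1", "a1", "a1"), c("b1", "b1", "b1"), sample = "s2"))
  r$cell_id <- sprintf("c%02d", 1:5)
  glob <- buildClonotypes(r, scope = "global")
  expect_identical(unname(cloneSizes(glob)), 5L)
  loc <- buildClonotypes(r, scope = "per_sample")
  expect_identical(sort(unname(cloneSizes(loc))), c(2L, 3L))
})

test_that("records with missing chains are rejected and counted", {
  r <- rec(c("a1", "", "a2", NA), c("b1", "b2", "b3", "b4"))
  expect_message(ct <- buildClonotypes(r), "2 record")
  expect_identical(nrow(clonotypeData(ct)), 2L)
  expect_identical(ct@rejected, 2L)
  expect_error(buildClonotypes(rec("", "b")), "chain")
})

test_that("clonality classes are a pure function of clone size", {
  r <- rec(c(rep("a1", 3), rep("a2", 2), "a3"),
           c(rep("b1", 3), rep("b2", 2), "b3"))
  ct <- classifyClonality(buildClonotypes(r))
  d <- clonotypeData(ct)
  expect_true(all(d$clonality[d$clone_size == 3] == "clonal"))
  expect_true(all(d$clonality[d$clone_size == 2] == "repeated"))
  expect_true(all(d$clonality[d$clone_size == 1] == "unique"))
  # partition: class counts sum to total cells
  expect_identical(sum(table(d$clonality)), nrow(d))
  # configurable threshold
  d5 <- clonotypeData(classifyClonality(buildClonotypes(r),
                                        clonalityConfig(clonalMinSize = 4)))
  expect_false(any(d5$clonality == "clonal"))
})

test_that("rarefied entropy hits its exact limits", {
  # monoclonal repertoire: H = 0 with zero spread
  mono <- classifyClonality(buildClonotypes(
    rec(rep("a1", 6), rep("b1", 6))))
  e <- rarefiedEntropy(mono, clonalityConfig(depth = 4, reps = 50))
  expect_equal(e$mean_entropy, 0)
  expect_equal(e$sd_entropy, 0)
  # all-distinct repertoire sampled at full depth: H = ln d exactly
  dist <- classifyClonality(buildClonotypes(
    rec(paste0("a", 1:5), paste0("b", 1:5))))
  e2 <- rarefiedEntropy(dist, clonalityConfig(depth = 5, reps = 20))
  expect_equal(e2$mean_entropy, log(5), tolerance = 1e-12)
  expect_equal(e2$sd_entropy, 0)
})

test_that("downsampled entropy matches the exhaustive-subsample expectation", {
  # repertoire {5, 5}: two clonotypes of five cells, depth 4
  r <- rec(rep(c("a1", "a2"), each = 5), rep(c("b1", "b2"), each = 5))
  ct <- classifyClonality(buildClonotypes(r))
  e <- rarefiedEntropy(ct, clonalityConfig(depth = 4, reps = 10000,
                                           seed = 42))
  exact <- oracle_rarefied_entropy(rep(c("A", "B"), each = 5), 4)
  expect_equal(e$mean_entropy, exact, tolerance = 0.02)
})

test_that("samples below depth are reported missing, never extrapolated", {
  r <- rbind(rec(paste0("a", 1:8), paste0("b", 1:8), sample = "big"),
             rec("a9", "b9", sample = "tiny"))
  r$cell_id <- sprintf("c%02d", 1:9)
  ct <- classifyClonality(buildClonotypes(r, scope = "per_sample"))
  e <- rarefiedEntropy(ct, clonalityConfig(depth = 5, reps = 30))
  expect_identical(e$reason[e$sample_id == "tiny"], "below_depth")
  expect_true(is.na(e$mean_entropy[e$sample_id == "tiny"]))
  expect_false(is.na(e$mean_entropy[e$sample_id == "big"]))
  # depth = "min" uses the smallest repertoire
  e2 <- rarefiedEntropy(ct, clonalityConfig(depth = "min", reps = 30))
  expect_identical(unique(e2$depth), 1L)
})

test_that("concentrating a repertoire never raises mean rarefied entropy", {
  set.seed(7)
  for (i in 1:5) {
    sizes <- sort(rpois(4, 3) + 1, decreasing = TRUE)
    sizes <- c(sizes, 1L)  # ensure a singleton to move
    ids <- rep(paste0("cl", seq_along(sizes)), sizes)
    mk <- function(v) {
      d <- data.frame(cell_id = sprintf("c%02d", seq_along(v)),
                      sample_id = "s", alpha = v, beta = v)
      classifyClonality(buildClonotypes(d))
    }
    before <- rarefiedEntropy(mk(ids),
                              clonalityConfig(depth = 4, reps = 2000,
                                              seed = i))$mean_entropy
    moved <- ids
    moved[moved == paste0("cl", length(sizes))] <- "cl1"
    after <- rarefiedEntropy(mk(moved),
                             clonalityConfig(depth = 4, reps = 2000,
                                             seed = i))$mean_entropy
    expect_lte(after, before + 0.02)
  }
})

test_that("synthetic enrichment shows up as excess clonal fraction", {
  set.seed(8)
  ann <- data.frame(cell_id = sprintf("c%03d", 1:300),
                    state = sample(c("S1", "S2", "S3"), 300, replace = TRUE),
                    patient = "P1")
  strict <- logical(20)
  for (s in 1:20) {
    ct <- simulateTcrTable(ann, tcrDesign(clonalEnrichment = 10, seed = s),
                           reactiveState = "S1")
    d <- clonotypeData(ct)
    st <- ann$state[match(d$cell_id, ann$cell_id)]
    fr <- mean(d$clonality[st == "S1"] == "clonal")
    fo <- mean(d$clonality[st != "S1"] == "clonal")
    strict[s] <- fr > fo
  }
  expect_true(all(strict))
})
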