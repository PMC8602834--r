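test_that("Kaplan-Meier curve reproduces hand product-limit values", {
  km <- kmCurve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))
  expect_equal(attr(km, "median"), 2)
  all_cens <- kmCurve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(all_cens$surv == 1))
  expect_true(is.na(attr(all_cens, "median")))
  single <- kmCurve(5, 1)
  expect_equal(single$surv, 0)
  expect_equal(attr(single, "median"), 5)
  expect_error(kmCurve(c(-1, 2), c(1, 1)), "positive")
})

test_that("log-rank test matches the hand O-E/V oracle and is symmetric", {
  # identical data in both groups
  lr0 <- logrankTest(rep(c(1, 2, 3), 2), rep(1, 6),
                     rep(c("A", "B"), each = 3))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)
  # A events at {1,2}, B events at {3,4}
  t <- c(1, 2, 3, 4)
  ev <- c(1, 1, 1, 1)
  g <- c("A", "A", "B", "B")
  lr <- logrankTest(t, ev, g)
  expect_equal(lr$statistic, oracle_logrank2(t, ev, g == "A"),
               tolerance = 1e-10)
  # label symmetry
  lr_swap <- logrankTest(t, ev, c("B", "B", "A", "A"))
  expect_equal(lr$statistic, lr_swap$statistic, tolerance = 1e-12)
  expect_error(logrankTest(t, ev, rep("A", 4)), "2 groups")
})

test_that("Cox fit maximizes the partial likelihood (grid-search oracle)", {
  # 6-subject toy with a binary covariate and a tie
  t <- c(2, 3, 3, 5, 7, 9)
  ev <- c(1, 1, 1, 0, 1, 1)
  x <- c(1, 1, 0, 1, 0, 0)
  f <- coxFit(x, t, ev)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, oracle_efron_loglik, numeric(1), x = x, times = t,
               events = ev)
  expect_equal(unname(coef(f)), grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(f@loglik, max(ll), tolerance = 1e-6)
  # AIC and HR identities
  expect_equal(f@aic, -2 * f@loglik + 2, tolerance = 1e-12)
  expect_equal(unname(hazardRatio(f)), exp(unname(coef(f))),
               tolerance = 1e-12)
})

test_that("Cox fit agrees with survival::coxph for both tie methods", {
  set.seed(30)
  n <- 70
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  tm <- round(rexp(n, 0.2 * exp(0.4 * x[, 1])), 1) + 0.05
  ev <- rbinom(n, 1, 0.8)
  for (ties in c("efron", "breslow")) {
    f <- coxFit(x, tm, ev, evalConfig(ties = ties))
    ref <- survival::coxph(survival::Surv(tm, ev) ~ x, ties = ties)
    expect_equal(unname(coef(f)), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(f@se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
    expect_equal(f@loglik, ref$loglik[2], tolerance = 1e-8)
  }
})

test_that("Cox reparameterization and degeneracy contracts hold", {
  set.seed(31)
  x <- rnorm(40)
  tm <- rexp(40, exp(0.5 * x))
  ev <- rep(1, 40)
  f1 <- coxFit(x, tm, ev)
  f2 <- coxFit(10 * x, tm, ev)
  expect_equal(unname(coef(f2)), unname(coef(f1)) / 10, tolerance = 1e-8)
  expect_equal(f1@loglik, f2@loglik, tolerance = 1e-10)
  expect_error(coxFit(rep(1, 40), tm, ev), "no information")
  # perfect separation is flagged, not silently returned
  xs <- c(rep(0, 10), rep(1, 10))
  ts <- c(seq(1, 10), seq(20, 29))
  fs <- coxFit(xs, ts, rep(1, 20))
  expect_true("monotone_likelihood" %in% fs@flags)
})

test_that("concordance matches brute-force pairs and survival::concordance", {
  expect_equal(concordanceIndex(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(concordanceIndex(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0)
  set.seed(32)
  for (i in 1:10) {
    n <- 20
    risk <- sample(1:6, n, replace = TRUE)
    tm <- sample(1:8, n, replace = TRUE)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) next
    c_pkg <- concordanceIndex(risk, tm, ev)
    expect_equal(c_pkg, oracle_cindex(risk, tm, ev), tolerance = 1e-12)
  }
  set.seed(33)
  risk <- rnorm(50)
  tm <- rexp(50, exp(0.5 * risk))
  ev <- rbinom(50, 1, 0.8)
  ref <- survival::concordance(survival::Surv(tm, ev) ~ risk,
                               reverse = TRUE)$concordance
  expect_equal(concordanceIndex(risk, tm, ev), unname(ref),
               tolerance = 1e-10)
})

test_that("time-dependent AUC: transcription oracle and censor-free limit", {
  # 8-subject worked instance with one censored observation
  risk <- c(2.1, 0.4, 1.5, 3.2, 0.9, 1.1, 2.8, 0.2)
  tm <- c(1, 5, 2, 1.5, 4, 6, 2.5, 7)
  ev <- c(1, 1, 1, 1, 0, 1, 1, 1)
  tstar <- 3
  expect_equal(timeDependentAUC(risk, tm, ev, tstar),
               oracle_td_auc(risk, tm, ev, tstar), tolerance = 1e-10)
  # without censoring it collapses to the binary pair-rule AUC
  set.seed(34)
  risk2 <- rnorm(60)
  tm2 <- rexp(60, exp(0.6 * risk2))
  lab <- ifelse(tm2 <= median(tm2), "case", "ctrl")
  a_td <- timeDependentAUC(risk2, tm2, rep(1, 60), median(tm2))
  a_bin <- unname(geneAUC(toy_expr(risk2), lab, "case"))
  expect_equal(a_td, a_bin, tolerance = 1e-10)
  expect_error(timeDependentAUC(risk2, tm2, rep(1, 60), min(tm2) / 2),
               "case")
})

test_that("RMST integrates the step curve exactly and handles limits", {
  # no events in either arm: RMST = tau, ratio 1
  r0 <- rmstRatio(c(4, 5, 6, 7), c(0, 0, 0, 0), c("A", "A", "B", "B"),
                  tau = 3)
  expect_equal(r0$arms$rmst, c(3, 3))
  expect_equal(r0$ratio, 1)
  # all events at t = 1, tau = 2: unit-step rectangle
  r1 <- rmstRatio(c(1, 1, 1, 2, 2, 2), c(1, 1, 1, 0, 0, 0),
                  rep(c("A", "B"), each = 3), tau = 2)
  expect_equal(r1$arms$rmst[r1$arms$arm == "A"], 1)
  # two 5-subject arms vs hand step integration
  tA <- c(1, 2, 4, 6, 9); eA <- c(1, 0, 1, 1, 0)
  tB <- c(2, 3, 5, 7, 8); eB <- c(1, 1, 0, 1, 1)
  r <- rmstRatio(c(tA, tB), c(eA, eB), rep(c("A", "B"), each = 5), tau = 7)
  expect_equal(r$arms$rmst[1], oracle_rmst(tA, eA, 7), tolerance = 1e-12)
  expect_equal(r$arms$rmst[2], oracle_rmst(tB, eB, 7), tolerance = 1e-12)
  expect_equal(r$ratio, oracle_rmst(tB, eB, 7) / oracle_rmst(tA, eA, 7),
               tolerance = 1e-12)
  expect_identical(r$ratio_order, "B / A")
  # arm A ends with a censored subject at t = 9, so tau = 9.5 is unreachable
  expect_error(rmstRatio(c(tA, tB), c(eA, eB), rep(c("A", "B"), each = 5),
                         tau = 9.5), "reduce tau")
  # SE agrees with the survfit restricted-mean machinery
  tab <- summary(survival::survfit(
    survival::Surv(c(tA, tB), c(eA, eB)) ~ rep(c("A", "B"), each = 5)),
    rmean = 7)$table
  expect_equal(r$arms$rmst, unname(tab[, "rmean"]), tolerance = 1e-8)
  expect_equal(r$arms$se, unname(tab[, "se(rmean)"]), tolerance = 1e-8)
})

test_that("median split sends ties to the low group and validates", {
  expect_identical(as.character(stratifyMedian(c(1, 2, 3, 4))),
                   c("low", "low", "high", "high"))
  expect_identical(as.character(stratifyMedian(c(1, 2, 3))),
                   c("low", "low", "high"))
  expect_identical(as.character(stratifyMedian(c(1, 2, 2, 2, 5))),
                   c("low", "low", "low", "low", "high"))
  expect_error(stratifyMedian(rep(3, 4)), "identical")
  expect_error(stratifyMedian(1), "2 samples")
})

test_that("linear risk scores combine coefficients, negation and strictness", {
  m <- rbind(gA = c(3, 1), gB = c(4, 2))
  colnames(m) <- c("s1", "s2")
  r <- linearRiskScore(m, c(gA = 2, gB = -1))
  expect_equal(unname(r), c(2, 0), ignore_attr = TRUE)
  expect_equal(unname(linearRiskScore(m, c(gA = 1))["s1"]), 3,
               ignore_attr = TRUE)
  expect_warning(r2 <- linearRiskScore(m, c(gA = 1, gX = 5)), "absent")
  expect_identical(attr(r2, "missing_genes"), "gX")
  expect_error(linearRiskScore(m, c(gA = 1, gX = 5), strict = TRUE), "gX")
  sv <- scoreSamples(rbind(m, gC = c(0, 0)), c("gA", "gB"),
                     scoringConfig(method = "mean"))
  expect_equal(unname(linearRiskScore(sv, negate = TRUE)),
               -unname(scores(sv)))
})

test_that("paired bootstrap C-index comparison separates clear cases", {
  set.seed(35)
  n <- 120
  u <- rnorm(n)
  tm <- rexp(n, exp(0.9 * u))
  ev <- rbinom(n, 1, 0.85)
  good <- u
  bad <- rnorm(n)
  cmp <- compareCIndex(good, bad, tm, ev,
                       evalConfig(bootstrapReps = 300, seed = 9))
  expect_gt(cmp$diff, 0)
  expect_lt(cmp$p_value, 0.05)
})
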