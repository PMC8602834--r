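# Independent oracle implementations used across the suite.  Each is written
# as a direct, unoptimized transcription of the defining formula (explicit
# loops, pair enumeration, exhaustive subsets) and shares no code with the
# package internals it checks.

# AUC by brute-force pair counting (ties half).
oracle_pair_auc <- function(values, positive) {
  pos <- values[positive]
  neg <- values[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Exact one/two-sided rank-sum p by enumerating all group assignments,
# statistic computed by pair counting (inclusive convention).
oracle_exact_wilcox <- function(x, positive,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  n1 <- sum(positive)
  u_of <- function(idx) {
    pos <- x[idx]
    neg <- x[-idx]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot
  }
  u_obs <- u_of(which(positive))
  sets <- utils::combn(n, n1)
  u_all <- apply(sets, 2, u_of)
  mu <- n1 * (n - n1) / 2
  eps <- 1e-9
  if (alternative == "greater") mean(u_all >= u_obs - eps)
  else min(1, mean(abs(u_all - mu) >= abs(u_obs - mu) - eps))
}

# Literal transcription of the kernel CDF statistic.
oracle_kcdf <- function(mat, kernel = "gaussian", r = 0.5) {
  out <- mat * NA
  n <- ncol(mat)
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    if (kernel == "gaussian") {
      h <- sd(x) / 4
      for (j in seq_len(n)) {
        s <- 0
        for (k in seq_len(n)) s <- s + pnorm((x[j] - x[k]) / h)
        out[i, j] <- s / n
      }
    } else {
      for (j in seq_len(n)) {
        s <- 0
        for (k in seq_len(n)) s <- s + ppois(x[j], lambda = x[k] + r)
        out[i, j] <- s / n
      }
    }
  }
  out
}

# Step-by-step weighted KS walk on one sample's gene statistic (kcdf flavor).
oracle_kcdf_walk <- function(z, in_set, tau = 1, es_mode = "max_diff") {
  p <- length(z)
  ord <- order(z, decreasing = TRUE)
  rnk <- integer(p)
  rnk[ord] <- seq_len(p)
  rtilde <- abs(p / 2 - rnk)
  denom_in <- sum((rtilde^tau)[in_set])
  k_out <- p - sum(in_set)
  run_in <- run_out <- 0
  devs <- numeric(p)
  for (step in seq_len(p)) {
    g <- ord[step]
    if (in_set[g]) run_in <- run_in + rtilde[g]^tau / denom_in
    else run_out <- run_out + 1 / k_out
    devs[step] <- run_in - run_out
  }
  if (es_mode == "max_abs") devs[which.max(abs(devs))]
  else max(c(0, devs[devs > 0])) - max(c(0, -devs[devs < 0]))
}

# Step-by-step rank-weighted KS walk (integrated difference) on one sample.
oracle_rwks_walk <- function(x, in_set, alpha = 0.25) {
  p <- length(x)
  rnk <- rank(x, ties.method = "average")
  ord <- order(x, decreasing = TRUE)
  denom_in <- sum((rnk^alpha)[in_set])
  k_out <- p - sum(in_set)
  run_in <- run_out <- 0
  total <- 0
  for (step in seq_len(p)) {
    g <- ord[step]
    if (in_set[g]) run_in <- run_in + rnk[g]^alpha / denom_in
    else run_out <- run_out + 1 / k_out
    total <- total + (run_in - run_out)
  }
  total
}

# Recovery-curve score by explicit enumeration of the step curve.
oracle_recovery <- function(sig_ranks, k, p, top_fraction) {
  thr <- ceiling(top_fraction * p)
  area <- 0
  for (i in seq_len(thr)) area <- area + sum(sig_ranks <= i)
  max_area <- 0
  for (i in seq_len(thr)) max_area <- max_area + min(i, k)
  area / max_area
}

# Efron partial log-likelihood by literal loops (single covariate).
oracle_efron_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    d <- length(D)
    s0r <- sum(exp(beta * x[R]))
    s0d <- sum(exp(beta * x[D]))
    ll <- ll + sum(beta * x[D])
    for (l in seq_len(d) - 1) ll <- ll - log(s0r - (l / d) * s0d)
  }
  ll
}

# Product-limit survival at time t, literal.
oracle_km_at <- function(times, events, t) {
  s <- 1
  for (u in sort(unique(times[events == 1 & times <= t]))) {
    n_risk <- sum(times >= u)
    d <- sum(times == u & events == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# Literal transcription of the KM-weighted cumulative/dynamic AUC.
oracle_td_auc <- function(risk, times, events, tstar) {
  S <- oracle_km_at(times, events, tstar)
  cuts <- sort(unique(risk), decreasing = TRUE)
  tp <- fp <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    grp <- risk >= cuts[i]
    px <- mean(grp)
    Sc <- oracle_km_at(times[grp], events[grp], tstar)
    tp[i] <- (1 - Sc) * px / (1 - S)
    fp[i] <- Sc * px / S
  }
  tp <- pmin(pmax(tp, 0), 1)
  fp <- pmin(pmax(fp, 0), 1)
  xx <- c(0, fp, 1)
  yy <- c(0, tp, 1)
  auc <- 0
  for (i in seq_len(length(xx) - 1))
    auc <- auc + (xx[i + 1] - xx[i]) * (yy[i] + yy[i + 1]) / 2
  auc
}

# RMST by explicit step integration of the product-limit curve.
oracle_rmst <- function(times, events, tau) {
  ut <- sort(unique(times[events == 1 & times <= tau]))
  area <- 0
  prev_t <- 0
  s <- 1
  for (u in ut) {
    area <- area + s * (u - prev_t)
    n_risk <- sum(times >= u)
    d <- sum(times == u & events == 1)
    s <- s * (1 - d / n_risk)
    prev_t <- u
  }
  area + s * (tau - prev_t)
}

# Harrell C by brute-force pair enumeration.
oracle_cindex <- function(risk, times, events) {
  num <- den <- 0
  n <- length(times)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- (times[i] < times[j] && events[i] == 1) ||
      (times[i] == times[j] && events[i] == 1 && events[j] == 0)
    if (!usable) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  num / den
}

# Two-group log-rank chi-square by explicit O-E/V accumulation.
oracle_logrank2 <- function(times, events, group1) {
  o <- e <- v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# Mean Shannon entropy over all depth-d subsamples (exhaustive).
oracle_rarefied_entropy <- function(repertoire, d) {
  sets <- utils::combn(length(repertoire), d)
  h <- apply(sets, 2, function(idx) {
    p <- table(repertoire[idx]) / d
    -sum(p * log(p))
  })
  mean(h)
}

# small labeled matrix helper
toy_expr <- function(values, genes = NULL, obs = NULL) {
  m <- matrix(values, nrow = if (is.null(genes)) 1 else length(genes))
  rownames(m) <- genes %||% "g1"
  colnames(m) <- obs %||% paste0("c", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a
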