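#' @include AllClasses.R
#' @importFrom survival Surv survfit survdiff
NULL

#' Evaluation configuration for survival metrics
#'
#' @param ties partial-likelihood tie handling: \code{"efron"} (default) or
#'   \code{"breslow"}.
#' @param tdaucTime evaluation horizon t* of the time-dependent AUC
#'   (NULL = median observed time).
#' @param rmstTau RMST horizon (NULL = minimum over arms of the largest
#'   observed time).
#' @param bootstrapReps paired bootstrap replicates for C-index comparison.
#' @param confLevel confidence level of reported intervals.
#' @param seed RNG seed for bootstrap procedures.
#' @export
evalConfig <- function(ties = c("efron", "breslow"), tdaucTime = NULL,
                       rmstTau = NULL, bootstrapReps = 1000,
                       confLevel = 0.95, seed = 1L) {
    ties <- match.arg(ties)
    structure(list(ties = ties, tdaucTime = tdaucTime, rmstTau = rmstTau,
                   bootstrapReps = as.integer(bootstrapReps),
                   confLevel = confLevel, seed = as.integer(seed)),
              class = "eval_config")
}

.check_surv <- function(times, events) {
    .stop_if(length(times) != length(events),
             "'times' and 'events' must have equal length")
    .stop_if(any(!is.finite(times)) || any(times <= 0),
             "survival times must be positive and finite")
    .stop_if(!all(events %in% c(0, 1)), "'events' must be 0/1")
}

#' Kaplan-Meier curve
#'
#' Product-limit estimate of the survival function with the median survival
#' time, defined as the first time at which the estimate drops to 0.5 or
#' below (missing when the curve never reaches 0.5).
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @return data.frame (time, n_risk, n_event, n_censor, surv) with the
#'   median attached as attribute \code{"median"}.
#' @examples
#' km <- kmCurve(c(1, 2, 3), c(1, 1, 1))
#' km$surv            # 2/3, 1/3, 0
#' attr(km, "median")
#' @export
kmCurve <- function(times, events) {
    .check_surv(times, events)
    fit <- survfit(Surv(times, events) ~ 1)
    out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
    med <- out$time[out$surv <= 0.5]
    attr(out, "median") <- if (length(med)) min(med) else NA_real_
    out
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank statistic over the pooled event
#' times, chi-squared with (number of groups - 1) degrees of freedom.
#'
#' @inheritParams kmCurve
#' @param groups group labels (>= 2 non-empty groups; >= 1 event overall).
#' @return list(statistic, df, p_value, observed, expected).
#' @export
logrankTest <- function(times, events, groups) {
    .check_surv(times, events)
    g <- factor(groups)
    .stop_if(nlevels(g) < 2, "need at least 2 groups")
    .stop_if(any(table(g) == 0), "every group must be non-empty")
    .stop_if(sum(events) < 1, "need at least one event")
    sd <- survdiff(Surv(times, events) ~ g)
    df <- nlevels(g) - 1L
    list(statistic = unname(sd$chisq), df = df,
         p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
         observed = unname(sd$obs), expected = unname(sd$exp))
}

## ---------------------------------------------------------------------------
## Cox proportional hazards (Newton-Raphson, Efron/Breslow ties)
## ---------------------------------------------------------------------------

# Partial log-likelihood, score and information at beta for sorted data.
.cox_derivs <- function(beta, x, times, events, ties) {
    n <- nrow(x)
    p <- ncol(x)
    eta <- drop(x %*% beta)
    w <- exp(eta)
    wx <- x * w
    # suffix (risk-set) sums: times sorted increasing, risk set = i..n
    S0 <- rev(cumsum(rev(w)))
    S1 <- apply(wx, 2L, function(col) rev(cumsum(rev(col))))
    S1 <- matrix(S1, n, p)
    # S2 suffix sums per coefficient pair
    S2 <- array(0, c(n, p, p))
    for (a in seq_len(p)) for (b in seq_len(p))
        S2[, a, b] <- rev(cumsum(rev(w * x[, a] * x[, b])))
    ll <- 0
    U <- numeric(p)
    info <- matrix(0, p, p)
    ev_times <- unique(times[events == 1])
    for (t in ev_times) {
        first <- match(TRUE, times >= t)   # risk set starts here
        Didx <- which(times == t & events == 1)
        d <- length(Didx)
        s0r <- S0[first]
        s1r <- S1[first, ]
        s2r <- S2[first, , , drop = FALSE][1, , ]
        ll <- ll + sum(eta[Didx])
        U <- U + colSums(x[Didx, , drop = FALSE])
        if (ties == "breslow") {
            ll <- ll - d * log(s0r)
            xbar <- s1r / s0r
            U <- U - d * xbar
            info <- info + d * (s2r / s0r - tcrossprod(xbar))
        } else {
            s0d <- sum(w[Didx])
            s1d <- colSums(wx[Didx, , drop = FALSE])
            s2d <- crossprod(x[Didx, , drop = FALSE] * w[Didx],
                             x[Didx, , drop = FALSE])
            for (l in seq_len(d) - 1L) {
                f <- l / d
                s0 <- s0r - f * s0d
                s1 <- s1r - f * s1d
                s2 <- s2r - f * s2d
                ll <- ll - log(s0)
                xbar <- s1 / s0
                U <- U - xbar
                info <- info + s2 / s0 - tcrossprod(xbar)
            }
        }
    }
    list(loglik = ll, score = U, info = matrix(info, p, p))
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the partial likelihood with Efron tie
#' handling (Breslow available via the configuration).  Standard errors come
#' from the inverse observed information.  Convergence requires every score
#' component below 1e-9 within 50 iterations; failure is reported in the
#' returned object, never silently.  A coefficient drifting beyond |beta| >
#' 15 is treated as monotone likelihood (perfect separation): the fit stops
#' with the coefficient capped and the \code{"monotone_likelihood"} flag
#' set.
#'
#' @param x covariate vector or n-by-p matrix (finite, non-constant).
#' @param times,events survival outcome as in \code{\link{kmCurve}}.
#' @param config an \code{\link{evalConfig}}.
#' @return a \linkS4class{CoxFit}.
#' @examples
#' set.seed(1)
#' x <- rnorm(50)
#' t <- rexp(50, exp(0.5 * x))
#' coxFit(x, t, rep(1, 50))
#' @export
coxFit <- function(x, times, events, config = evalConfig()) {
    .check_surv(times, events)
    .stop_if(sum(events) < 1, "need at least one event")
    x <- as.matrix(x)
    if (is.null(colnames(x)))
        colnames(x) <- if (ncol(x) == 1) "x" else paste0("x", seq_len(ncol(x)))
    .stop_if(nrow(x) != length(times),
             "'x' must have one row per subject")
    .stop_if(any(!is.finite(x)), "covariates must be finite")
    sds <- apply(x, 2L, stats::sd)
    .stop_if(any(sds == 0),
             "no information: constant covariate(s) ",
             paste(colnames(x)[sds == 0], collapse = ", "))
    ord <- order(times)
    xs <- x[ord, , drop = FALSE]
    ts <- times[ord]
    ev <- events[ord]
    p <- ncol(x)
    beta <- numeric(p)
    flags <- character()
    converged <- FALSE
    iter <- 0L
    cap <- 15
    repeat {
        iter <- iter + 1L
        dv <- .cox_derivs(beta, xs, ts, ev, config$ties)
        if (max(abs(dv$score)) < 1e-9) {
            converged <- TRUE
            break
        }
        step <- tryCatch(solve(dv$info, dv$score), error = function(e) NULL)
        if (is.null(step)) {
            flags <- c(flags, "singular_information")
            break
        }
        beta <- beta + step
        if (any(abs(beta) > cap)) {
            flags <- c(flags, "monotone_likelihood")
            beta <- pmin(pmax(beta, -cap), cap)
            dv <- .cox_derivs(beta, xs, ts, ev, config$ties)
            break
        }
        if (iter >= 50L) {
            flags <- c(flags, "max_iterations")
            break
        }
    }
    vc <- tryCatch(solve(dv$info), error = function(e)
        matrix(NA_real_, p, p))
    ll0 <- .cox_derivs(numeric(p), xs, ts, ev, config$ties)$loglik
    names(beta) <- colnames(x)
    new("CoxFit", coef = beta, se = sqrt(pmax(diag(vc), 0)),
        vcov = vc, loglik = dv$loglik, loglik0 = ll0,
        aic = -2 * dv$loglik + 2 * p,
        n = length(ts), nevent = as.integer(sum(ev)), iter = iter,
        converged = converged, flags = flags, ties = config$ties)
}

#' Harrell's concordance index
#'
#' Over usable pairs -- those in which the subject with the shorter time has
#' an event (pairs with tied times and both events are unusable; a tied time
#' between an event and a censored subject counts the event as shorter) --
#' the fraction in which the higher risk goes with the shorter time, risk
#' ties counted one half.
#'
#' @param risk numeric risk scores (higher = worse prognosis expected).
#' @inheritParams kmCurve
#' @return the concordance index in [0, 1].
#' @export
concordanceIndex <- function(risk, times, events) {
    .check_surv(times, events)
    .stop_if(length(risk) != length(times),
             "'risk' must match the outcome length")
    dt <- outer(times, times, "<")
    te <- outer(times, times, "==")
    ev_i <- matrix(events == 1, length(times), length(times))
    usable <- (dt & ev_i) | (te & ev_i & t(!ev_i))
    .stop_if(!any(usable), "no usable pair")
    rr_gt <- outer(risk, risk, ">")[usable]
    rr_eq <- outer(risk, risk, "==")[usable]
    (sum(rr_gt) + 0.5 * sum(rr_eq)) / sum(usable)
}

# KM survival probability at time t (product-limit; findInterval for speed)
.km_at <- function(times, events, t) {
    et <- times[events == 1 & times <= t]
    if (!length(et)) return(1)
    ut <- sort(unique(et))
    st <- sort(times)
    n <- length(times)
    nrisk <- n - findInterval(ut, st, left.open = TRUE)
    d <- as.numeric(table(factor(et, levels = ut)))
    prod(1 - d / nrisk)
}

#' Time-dependent ROC AUC (cumulative/dynamic, KM-weighted)
#'
#' Cases at horizon t* are subjects with an event by t*, controls those
#' still at risk beyond t*.  True- and false-positive rates at a risk
#' cutoff c are estimated with Kaplan-Meier censoring weighting:
#' \code{TP(c) = (1 - S(t* | X > c)) P(X > c) / (1 - S(t*))} and
#' \code{FP(c) = S(t* | X > c) P(X > c) / S(t*)}, where S(. | X > c) is the
#' KM curve within the cutoff-exceeding subgroup and S the overall KM
#' curve.  The AUC is the trapezoid integral over the cutoff grid of unique
#' risk values.  (The estimator is not guaranteed monotone in c; points are
#' clamped to [0, 1].)
#'
#' @inheritParams concordanceIndex
#' @param tstar evaluation horizon, within the observed follow-up.
#' @return AUC at t*.
#' @export
timeDependentAUC <- function(risk, times, events, tstar) {
    .check_surv(times, events)
    .stop_if(length(risk) != length(times),
             "'risk' must match the outcome length")
    .stop_if(tstar <= 0 || tstar > max(times),
             "'tstar' must lie within the observed follow-up")
    S <- .km_at(times, events, tstar)
    .stop_if(S >= 1, "no case (event by t*)")
    .stop_if(S <= 0, "no control (at risk beyond t*)")
    cuts <- sort(unique(risk), decreasing = TRUE)
    n <- length(risk)
    tp <- fp <- numeric(length(cuts))
    for (i in seq_along(cuts)) {
        grp <- risk >= cuts[i]
        px <- mean(grp)
        Sc <- .km_at(times[grp], events[grp], tstar)
        tp[i] <- (1 - Sc) * px / (1 - S)
        fp[i] <- Sc * px / S
    }
    tp <- pmin(pmax(tp, 0), 1)
    fp <- pmin(pmax(fp, 0), 1)
    xx <- c(0, fp, 1)
    yy <- c(0, tp, 1)
    sum((xx[-1] - xx[-length(xx)]) * (yy[-1] + yy[-length(yy)]) / 2)
}

# RMST and its Greenwood-based variance for one arm up to tau.  tau beyond
# the last observed time is only allowed when the KM curve has already
# reached zero there (the integral is then identified; otherwise error).
.rmst_arm <- function(times, events, tau) {
    if (tau > max(times)) {
        last <- max(times)
        at_last <- times == last
        .stop_if(!(all(events[at_last] == 1) &&
                       sum(times > last) == 0 &&
                       .km_at(times, events, last) == 0),
                 "tau exceeds an arm's largest observed time; reduce tau")
    }
    ut <- sort(unique(times[events == 1 & times <= tau]))
    st <- sort(times)
    n <- length(times)
    if (!length(ut))
        return(list(rmst = tau, var = 0))
    nrisk <- n - findInterval(ut, st, left.open = TRUE)
    d <- as.numeric(table(factor(times[events == 1 & times <= tau],
                                 levels = ut)))
    surv <- cumprod(1 - d / nrisk)
    # step integral of S(t) on [0, tau]
    grid <- c(0, ut, tau)
    sgrid <- c(1, surv)
    rmst <- sum(sgrid * diff(grid))
    # area from each event time to tau, for the variance
    a <- rev(cumsum(rev(sgrid[-1] * diff(grid)[-1])))
    denom <- nrisk * (nrisk - d)
    term <- ifelse(denom > 0, a^2 * d / denom, 0)
    list(rmst = rmst, var = sum(term))
}

#' Restricted mean survival time ratio between two arms
#'
#' RMST is the area under each arm's Kaplan-Meier curve on [0, tau] (exact
#' step integration).  The ratio is arm2 / arm1 in the order of the factor
#' levels of \code{groups} (reported explicitly in the output); its
#' confidence interval uses the delta method on the log ratio with
#' Greenwood-based per-arm variances.
#'
#' @inheritParams logrankTest
#' @param tau horizon; defaults to the minimum over arms of the largest
#'   observed time.  Must not exceed either arm's follow-up.
#' @param confLevel confidence level.
#' @return list(arms, tau, ratio, ratio_ci, ratio_order).
#' @export
rmstRatio <- function(times, events, groups, tau = NULL, confLevel = 0.95) {
    .check_surv(times, events)
    g <- factor(groups)
    .stop_if(nlevels(g) != 2, "exactly two arms are required")
    t1 <- times[g == levels(g)[1]]
    e1 <- events[g == levels(g)[1]]
    t2 <- times[g == levels(g)[2]]
    e2 <- events[g == levels(g)[2]]
    if (is.null(tau)) tau <- min(max(t1), max(t2))
    .stop_if(tau <= 0, "'tau' must be positive")
    a1 <- .rmst_arm(t1, e1, tau)
    a2 <- .rmst_arm(t2, e2, tau)
    ratio <- a2$rmst / a1$rmst
    se_log <- sqrt(a1$var / a1$rmst^2 + a2$var / a2$rmst^2)
    z <- stats::qnorm(1 - (1 - confLevel) / 2)
    ci <- if (se_log > 0) exp(log(ratio) + c(-1, 1) * z * se_log)
          else c(ratio, ratio)
    list(arms = data.frame(arm = levels(g),
                           n = c(length(t1), length(t2)),
                           rmst = c(a1$rmst, a2$rmst),
                           se = sqrt(c(a1$var, a2$var))),
         tau = tau, ratio = ratio, ratio_ci = ci,
         ratio_order = paste(levels(g)[2], "/", levels(g)[1]))
}

#' Median-split stratification
#'
#' Scores strictly above the cohort median go to \code{"high"}; scores at
#' or below the median (including all ties at the median) go to
#' \code{"low"}.
#'
#' @param scores numeric vector or \linkS4class{ScoreVector} (>= 2 values).
#' @return factor with levels \code{low}, \code{high}, named by observation.
#' @export
stratifyMedian <- function(scores) {
    s <- if (is(scores, "ScoreVector")) scores(scores) else scores
    .stop_if(length(s) < 2, "need at least 2 samples")
    .stop_if(length(unique(s)) == 1,
             "all scores identical; a median split is undefined")
    med <- stats::median(s)
    g <- factor(ifelse(s > med, "high", "low"), levels = c("low", "high"))
    .stop_if(any(table(g) == 0),
             "median split produced an empty group")
    names(g) <- names(s)
    g
}

#' Coefficient-based linear risk score
#'
#' \code{risk_j = sum_g coef_g * expr_gj} over the coefficient genes present
#' in the matrix; absent genes are reported (and are an error in strict
#' mode, mirroring the rule that a signature is only evaluated in a cohort
#' where all its genes are detected).  For score-type signatures whose high
#' values mean good prognosis, \code{negate = TRUE} implements the
#' negative-score risk convention.
#'
#' @param x expression matrix / \linkS4class{ReactivityExperiment}, or a
#'   \linkS4class{ScoreVector} (then only \code{negate} applies).
#' @param coefficients named coefficient vector (ignored for ScoreVector
#'   input).
#' @param negate flip the sign of the result.
#' @param strict error when any coefficient gene is absent.
#' @return named numeric risk vector (absent genes in attribute
#'   \code{"missing_genes"} for matrix input).
#' @export
linearRiskScore <- function(x, coefficients = NULL, negate = FALSE,
                            strict = FALSE) {
    if (is(x, "ScoreVector")) {
        s <- scores(x)
        return(if (negate) -s else s)
    }
    mat <- .expr_input(x)$values
    .stop_if(is.null(names(coefficients)) || !length(coefficients),
             "'coefficients' must be a named vector")
    present <- intersect(names(coefficients), rownames(mat))
    missing <- setdiff(names(coefficients), present)
    .stop_if(!length(present), "none of the coefficient genes are present")
    .stop_if(strict && length(missing) > 0,
             "missing coefficient gene(s): ",
             paste(missing, collapse = ", "))
    if (length(missing))
        warning("coefficient gene(s) absent and skipped: ",
                paste(missing, collapse = ", "))
    risk <- drop(crossprod(mat[present, , drop = FALSE],
                           coefficients[present]))
    if (negate) risk <- -risk
    attr(risk, "missing_genes") <- missing
    risk
}

#' Paired-bootstrap comparison of two C-indices
#'
#' Resamples subjects with replacement, recomputes both concordance indices
#' on each replicate, and summarizes the paired difference (percentile CI
#' and a two-sided bootstrap p-value for difference = 0).
#'
#' @param risk1,risk2 two risk score vectors over the same subjects.
#' @inheritParams kmCurve
#' @param config an \code{\link{evalConfig}} (reps, confidence level, seed).
#' @return list(c1, c2, diff, ci, p_value, reps).
#' @export
compareCIndex <- function(risk1, risk2, times, events,
                          config = evalConfig()) {
    c1 <- concordanceIndex(risk1, times, events)
    c2 <- concordanceIndex(risk2, times, events)
    n <- length(times)
    diffs <- .with_seed(config$seed, {
        vapply(seq_len(config$bootstrapReps), function(b) {
            idx <- sample.int(n, n, replace = TRUE)
            tryCatch(
                concordanceIndex(risk1[idx], times[idx], events[idx]) -
                    concordanceIndex(risk2[idx], times[idx], events[idx]),
                error = function(e) NA_real_)
        }, numeric(1))
    })
    diffs <- diffs[is.finite(diffs)]
    alpha <- 1 - config$confLevel
    p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
    list(c1 = c1, c2 = c2, diff = c1 - c2,
         ci = unname(stats::quantile(diffs, c(alpha / 2, 1 - alpha / 2))),
         p_value = min(1, p), reps = length(diffs))
}
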