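# Survival machinery: median split, KM + log-rank, Cox fits, Harrell's C,
# repeated cross-validated model comparison, and the ISS / R-ISS / R2-ISS
# staging rules. Cox, KM and log-rank computations are delegated to the
# survival package; Harrell's C follows the explicit usable-pair contract
# (ties in risk count one half; tied times are unusable).

#' Split samples at the median score
#'
#' High iff score strictly exceeds the median; scores equal to the median go
#' to "low" (deterministic tie policy).
#'
#' @param scores numeric vector, >= 2 values, not all identical.
#' @return factor with levels \code{low}, \code{high} (names preserved).
#' @export
medianSplit <- function(scores) {
  if (length(scores) < 2L) stop("need >= 2 samples")
  med <- median(scores)
  if (all(scores == scores[[1L]])) stop("all scores identical: degenerate split")
  f <- factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
  names(f) <- names(scores)
  f
}

#' Kaplan-Meier curves and log-rank test
#'
#' @param times non-negative survival times.
#' @param events 0/1 event indicators (>= 1 event overall).
#' @param groups group labels, every group non-empty.
#' @return list with \code{fit} (a \code{survfit} object of product-limit
#'   curves per group), \code{chisq}, \code{df}, \code{p_value}.
#' @export
kmLogrank <- function(times, events, groups) {
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) == 0L)) stop("a group is empty")
  if (sum(events) == 0) stop("no events observed")
  surv <- survival::Surv(times, events)
  fit <- survival::survfit(surv ~ groups)
  sd <- survival::survdiff(surv ~ groups)
  df <- length(sd$n) - 1L
  list(fit = fit, chisq = unname(sd$chisq), df = df,
       p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Thin, validated wrapper around \code{survival::coxph} returning per
#' covariate the log-hazard coefficient, hazard ratio, Wald 95\% CI and p,
#' plus the model log partial likelihood and a convergence flag. Monotone
#' likelihood (complete separation) is reported, not hidden: the flag is
#' FALSE and the affected coefficients carry their diverged sign.
#'
#' @param times,events survival outcome.
#' @param covariates data.frame (or matrix/vector) of covariates; none may
#'   be constant.
#' @param ties "efron" (default) or "breslow".
#' @return list with \code{coefficients} data.frame (coef, hr, ci_lower,
#'   ci_upper, p_value), \code{loglik}, \code{converged}, \code{fit}.
#' @export
coxFit <- function(times, events, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(events) == 0) stop("no events observed")
  covariates <- as.data.frame(covariates)
  if (is.null(colnames(covariates)) || any(!nzchar(colnames(covariates))))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  for (nm in colnames(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v) && sd(v, na.rm = TRUE) == 0)
      stop(sprintf("covariate '%s' is constant", nm))
  }
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fm <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                paste(colnames(covariates), collapse = " + ")))
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fm, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w)))
        diverged <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  converged <- !diverged && all(is.finite(co[, "se(coef)"])) &&
    all(abs(co[, "coef"]) < 15)
  list(coefficients = data.frame(
         covariate = rownames(co),
         coef = co[, "coef"],
         hr = exp(co[, "coef"]),
         ci_lower = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
         ci_upper = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
         p_value = co[, "Pr(>|z|)"],
         row.names = NULL, stringsAsFactors = FALSE),
       loglik = fit$loglik[length(fit$loglik)],
       converged = converged,
       fit = fit)
}

#' Harrell's concordance index
#'
#' A pair is usable when the strictly smaller time carries an event; the
#' pair is concordant when the shorter-lived sample has the higher risk
#' score, and risk ties count one half.
#'
#' @param times,events survival outcome.
#' @param risks per-sample risk scores (higher = worse expected survival).
#' @return concordance in [0, 1].
#' @export
harrellC <- function(times, events, risks) {
  n <- length(times)
  stopifnot(length(events) == n, length(risks) == n)
  conc <- 0; usable <- 0
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    later <- times > times[i]
    usable <- usable + sum(later)
    conc <- conc + sum(risks[i] > risks[later]) + 0.5 * sum(risks[i] == risks[later])
  }
  if (usable == 0) stop("no usable pairs")
  conc / usable
}

#' Repeated cross-validated Cox model comparison
#'
#' For each of \code{repeats} repeats, samples are split into \code{folds}
#' folds stratified by event status; each candidate model is fitted on the
#' training folds and its held-out Harrell's C recorded, giving
#' repeats x folds C values per model. Models are compared pairwise with a
#' paired Wilcoxon test on the per-fold C values.
#'
#' @param clinical data.frame containing the outcome and covariate columns.
#' @param modelSpecs named list of character vectors of covariate column
#'   names, one per candidate model.
#' @param timeCol,eventCol outcome column names (default os_time/os_event).
#' @param repeats,folds cross-validation design (default 100 x 5).
#' @param seed integer seed; the result is a pure function of
#'   (inputs, seed).
#' @param ties passed to \code{\link{coxFit}}.
#' @return list with \code{c_values} (matrix, repeats*folds x models),
#'   \code{mean_c}, \code{pairwise_p} (paired two-sided Wilcoxon).
#' @export
cvCompareModels <- function(clinical, modelSpecs, timeCol = "os_time",
                            eventCol = "os_event", repeats = 100L,
                            folds = 5L, seed = 1L, ties = "efron") {
  if (is.null(names(modelSpecs)))
    names(modelSpecs) <- paste0("model", seq_along(modelSpecs))
  covars <- unique(unlist(modelSpecs))
  need <- c(timeCol, eventCol, covars)
  missing <- setdiff(need, colnames(clinical))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  dat <- clinical[complete.cases(clinical[, need, drop = FALSE]), , drop = FALSE]
  if (nrow(dat) < 10L * length(covars))
    stop("too few complete cases for the number of covariates")
  dat <- dat[order(rownames(dat)), , drop = FALSE]  # order-invariance
  n <- nrow(dat)
  ev <- dat[[eventCol]]
  cvals <- withr_seed(seed, {
    out <- matrix(NA_real_, repeats * folds, length(modelSpecs),
                  dimnames = list(NULL, names(modelSpecs)))
    for (r in seq_len(repeats)) {
      foldId <- .stratifiedFolds(ev, folds)
      for (f in seq_len(folds)) {
        test <- foldId == f
        if (sum(ev[test]) == 0 || sum(ev[!test]) == 0) next
        for (mi in seq_along(modelSpecs)) {
          spec <- modelSpecs[[mi]]
          fitted <- coxFit(dat[[timeCol]][!test], ev[!test],
                           dat[!test, spec, drop = FALSE], ties = ties)
          lp <- as.matrix(dat[test, spec, drop = FALSE]) %*%
            fitted$coefficients$coef
          out[(r - 1L) * folds + f, mi] <-
            tryCatch(harrellC(dat[[timeCol]][test], ev[test], as.vector(lp)),
                     error = function(e) NA_real_)
        }
      }
    }
    out
  })
  keep <- complete.cases(cvals)
  cvals <- cvals[keep, , drop = FALSE]
  k <- length(modelSpecs)
  pw <- matrix(NA_real_, k, k, dimnames = list(names(modelSpecs),
                                               names(modelSpecs)))
  for (a in seq_len(k)) for (b in seq_len(k)) if (a < b) {
    d <- cvals[, a] - cvals[, b]
    p <- if (all(d == 0)) 1 else
      suppressWarnings(wilcox.test(cvals[, a], cvals[, b],
                                   paired = TRUE, exact = FALSE)$p.value)
    pw[a, b] <- pw[b, a] <- p
  }
  diag(pw) <- 1
  list(c_values = cvals, mean_c = colMeans(cvals), pairwise_p = pw)
}

# fold assignment stratified by event indicator: events and non-events are
# each dealt round-robin after shuffling
.stratifiedFolds <- function(events, folds) {
  id <- integer(length(events))
  for (g in unique(events)) {
    idx <- which(events == g)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

#' International Staging System (ISS)
#'
#' Stage III when beta-2-microglobulin >= 5.5 mg/L; stage I when B2M <
#' 3.5 mg/L and albumin >= 3.5 g/dL; otherwise stage II. Missing inputs
#' propagate as NA.
#'
#' @param b2m beta-2-microglobulin, mg/L.
#' @param albumin serum albumin, g/dL.
#' @return integer stage 1/2/3 (NA on missing input).
#' @export
stageISS <- function(b2m, albumin) {
  out <- ifelse(is.na(b2m) | is.na(albumin), NA_integer_,
         ifelse(b2m >= 5.5, 3L,
         ifelse(b2m < 3.5 & albumin >= 3.5, 1L, 2L)))
  out
}

#' Revised ISS (R-ISS)
#'
#' Stage I: ISS I with no high-risk cytogenetics (del(17p), t(4;14),
#' t(14;16)) and normal LDH. Stage III: ISS III with high-risk cytogenetics
#' or elevated LDH. Everything else: stage II.
#'
#' @param iss ISS stage 1/2/3.
#' @param highRiskCA logical: del(17p) or t(4;14) or t(14;16) present.
#' @param ldhHigh logical: LDH above the upper limit of normal.
#' @return integer stage 1/2/3 (NA on missing input).
#' @export
stageRISS <- function(iss, highRiskCA, ldhHigh) {
  ifelse(is.na(iss) | is.na(highRiskCA) | is.na(ldhHigh), NA_integer_,
  ifelse(iss == 1L & !highRiskCA & !ldhHigh, 1L,
  ifelse(iss == 3L & (highRiskCA | ldhHigh), 3L, 2L)))
}

#' Second revision of the ISS (R2-ISS)
#'
#' Additive score: ISS II = 1, ISS III = 1.5, del(17p) = 1, high LDH = 1,
#' t(4;14) = 1, 1q gain/amplification = 0.5. Groups: 0 Low; 0.5-1 Low-Int;
#' 1.5-2.5 Int-High; 3-5 High.
#'
#' @param iss ISS stage 1/2/3.
#' @param del17p,t4_14,gain1q,ldhHigh logical risk flags.
#' @return data.frame with \code{score} and ordered factor \code{group}.
#' @export
stageR2ISS <- function(iss, del17p, t4_14, gain1q, ldhHigh) {
  score <- ifelse(is.na(iss) | is.na(del17p) | is.na(t4_14) |
                  is.na(gain1q) | is.na(ldhHigh), NA_real_,
    (iss == 2L) * 1 + (iss == 3L) * 1.5 + del17p * 1 + ldhHigh * 1 +
      t4_14 * 1 + gain1q * 0.5)
  group <- cut(score, breaks = c(-0.1, 0.25, 1.25, 2.75, 5.1),
               labels = c("Low", "Low-Int", "Int-High", "High"),
               ordered_result = TRUE)
  data.frame(score = score, group = group)
}
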