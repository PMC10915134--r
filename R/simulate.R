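# Synthetic-cohort generators. Every generator is a pure function of
# (parameters, seed) and records its truth in a SimTruth object so that
# parameter-recovery tests can compare estimates with the values that
# generated the data. A latent per-sample malignancy level lambda in [0,1]
# drives everything: marker perturbation, survival hazard, disease stage,
# mutation probability and TMB, and immune composition of the paired
# whole bone marrow.

#' Simulate CD138+ expression with perturbed plasma-cell markers
#'
#' Background genes are Normal(mu_g, noiseSd) with gene means mu_g ~
#' Normal(6, 1.5) on the log2 scale. Marker genes sit 2 log2-units above
#' background at lambda = 0 and are shifted by -lambda * delta (a
#' configurable fraction shifts +lambda * delta instead, modelling
#' two-sided perturbation; default 20\% up).
#'
#' @param nSamples number of samples.
#' @param nGenes genes in the universe (default 2000).
#' @param nMarkers plasma-marker genes (default 50).
#' @param delta marker shift per unit lambda, log2 units (default 2).
#' @param noiseSd residual sd, log2 units (default 0.5).
#' @param lambda per-sample malignancy in [0,1]; \code{NULL} draws
#'   Uniform(0,1).
#' @param upFraction fraction of markers perturbed upward (default 0.2).
#' @param seed integer seed.
#' @return list with \code{expr} (genes x samples matrix), \code{truth}
#'   (\linkS4class{SimTruth}), \code{signature} (the plasma-marker
#'   \linkS4class{GeneSignature}).
#' @export
simulateExpression <- function(nSamples, nGenes = 2000L, nMarkers = 50L,
                               delta = 2, noiseSd = 0.5, lambda = NULL,
                               upFraction = 0.2, seed = 1L) {
  if (nMarkers >= nGenes) stop("nMarkers must be < nGenes")
  if (delta < 0) stop("delta must be >= 0")
  withr_seed(seed, {
    if (is.null(lambda)) lambda <- runif(nSamples)
    if (length(lambda) != nSamples) stop("lambda length must be nSamples")
    if (any(lambda < 0 | lambda > 1)) stop("lambda must lie in [0,1]")
    genes <- sprintf("G%05d", seq_len(nGenes))
    samples <- sprintf("S%04d", seq_len(nSamples))
    markers <- genes[seq_len(nMarkers)]
    nUp <- round(upFraction * nMarkers)
    dirn <- rep(c(-1, 1), c(nMarkers - nUp, nUp))   # down then up markers
    mu <- rnorm(nGenes, 6, 1.5)
    mu[seq_len(nMarkers)] <- mu[seq_len(nMarkers)] + 2
    shift <- outer(dirn * delta, lambda)            # nMarkers x nSamples
    expr <- matrix(rnorm(nGenes * nSamples, mean = mu, sd = noiseSd),
                   nGenes, nSamples, dimnames = list(genes, samples))
    expr[seq_len(nMarkers), ] <- expr[seq_len(nMarkers), ] + shift
    truth <- new("SimTruth", lambda = setNames(lambda, samples),
                 params = list(nGenes = nGenes, nMarkers = nMarkers,
                               delta = delta, noiseSd = noiseSd,
                               upFraction = upFraction,
                               markerDirection = setNames(dirn, markers)),
                 seed = as.integer(seed))
    list(expr = expr, truth = truth,
         signature = GeneSignature("PlasmaB", markers))
  })
}

#' Simulate survival driven by latent malignancy
#'
#' Event times are Exponential(rate * exp(beta * lambda)); censoring is
#' independent Uniform(0, u) with u calibrated so the expected censoring
#' fraction matches \code{censorFrac}.
#'
#' @param truth \linkS4class{SimTruth} carrying lambda.
#' @param beta log hazard ratio per unit lambda.
#' @param rate baseline exponential rate (events per month).
#' @param censorFrac target censoring fraction in [0, 1).
#' @param seed integer seed.
#' @return data.frame with sample_id, os_time, os_event.
#' @export
simulateSurvival <- function(truth, beta = log(1.72), rate = 0.02,
                             censorFrac = 0.3, seed = 1L) {
  if (rate <= 0) stop("rate must be positive")
  if (censorFrac < 0 || censorFrac >= 1)
    stop("censorFrac must lie in [0, 1)")
  lam <- simLambda(truth)
  rates <- rate * exp(beta * lam)
  withr_seed(seed, {
    t <- rexp(length(lam), rate = rates)
    if (censorFrac == 0) {
      time <- t; event <- rep(1L, length(t))
    } else {
      censProb <- function(u) mean((1 - exp(-rates * u)) / (rates * u))
      # censProb decreases from 1 (u -> 0) to 0 (u -> Inf)
      u <- uniroot(function(u) censProb(u) - censorFrac,
                   lower = 1e-6, upper = 1e8, tol = 1e-8)$root
      cens <- runif(length(t), 0, u)
      event <- as.integer(t <= cens)
      time <- pmin(t, cens)
    }
    data.frame(sample_id = names(lam), os_time = time, os_event = event,
               stringsAsFactors = FALSE)
  })
}

#' Assign disease stages from latent malignancy
#'
#' Stage = number of thresholds below lambda, mapped onto the ordered
#' vocabulary Healthy < MGUS < SMM < NDMM < RRMM.
#'
#' @param truth \linkS4class{SimTruth}.
#' @param thresholds strictly increasing cut points in [0,1] (default
#'   0.1, 0.3, 0.5, 0.7).
#' @return ordered factor of stage labels, named by sample.
#' @export
simulateStages <- function(truth, thresholds = c(0.1, 0.3, 0.5, 0.7)) {
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  if (length(thresholds) != 4L) stop("need 4 thresholds for 5 stages")
  lam <- simLambda(truth)
  idx <- vapply(lam, function(x) sum(x > thresholds), 0L) + 1L
  setNames(factor(STAGE_LEVELS[idx], levels = STAGE_LEVELS, ordered = TRUE),
           names(lam))
}

#' Simulate somatic mutations coupled to latent malignancy
#'
#' Each driver gene g mutates with probability logistic(a_g + b_g * lambda);
#' an additional per-sample nonsynonymous count ~ Poisson(exp(c + d *
#' lambda)) is spread over dummy passenger genes, so TMB rises with lambda.
#'
#' @param truth \linkS4class{SimTruth}.
#' @param driverGenes data.frame with columns gene, intercept, slope
#'   (logit scale).
#' @param tmbIntercept,tmbSlope log-scale Poisson coupling for the
#'   passenger count.
#' @param nPassengerGenes pool of dummy passenger gene names.
#' @param seed integer seed.
#' @return mutation data.frame (sample_id, gene, variant_classification).
#' @export
simulateMutations <- function(truth, driverGenes,
                              tmbIntercept = log(20), tmbSlope = 1,
                              nPassengerGenes = 200L, seed = 1L) {
  lam <- simLambda(truth)
  withr_seed(seed, {
    recs <- list()
    for (i in seq_len(nrow(driverGenes))) {
      p <- stats::plogis(driverGenes$intercept[i] +
                           driverGenes$slope[i] * lam)
      hit <- rbinom(length(lam), 1L, p) == 1L
      if (any(hit))
        recs[[length(recs) + 1L]] <- data.frame(
          sample_id = names(lam)[hit], gene = driverGenes$gene[i],
          variant_classification = "Missense_Mutation",
          stringsAsFactors = FALSE)
    }
    extra <- rpois(length(lam), exp(tmbIntercept + tmbSlope * lam))
    pool <- sprintf("PASS%04d", seq_len(nPassengerGenes))
    for (s in which(extra > 0L))
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = names(lam)[s],
        gene = sample(pool, extra[s], replace = TRUE),
        variant_classification = "Missense_Mutation",
        stringsAsFactors = FALSE)
    out <- do.call(rbind, recs)
    if (is.null(out))
      out <- data.frame(sample_id = character(), gene = character(),
                        variant_classification = character(),
                        stringsAsFactors = FALSE)
    out[order(out$sample_id, out$gene), , drop = FALSE]
  })
}

#' Disjoint immune cell-type marker signatures over a gene universe
#'
#' @param nCellTypes number of cell types (default 16).
#' @param genesPerSignature markers per cell type (default 30).
#' @param nGenes size of the gene universe.
#' @param cellTypes optional cell-type names.
#' @return named list of \linkS4class{GeneSignature}.
#' @export
simulateSignatures <- function(nCellTypes = 16L, genesPerSignature = 30L,
                               nGenes = 2000L, cellTypes = NULL) {
  if (nCellTypes * genesPerSignature >= nGenes)
    stop("gene universe too small for disjoint signatures")
  if (is.null(cellTypes))
    cellTypes <- c("PlasmaB", "NaiveB", "MemoryB", "CD8T", "CD4T", "NKresting",
                   "NKactivated", "Monocyte", "MacrophageM1", "MacrophageM2",
                   "Dendritic", "Neutrophil", "Eosinophil", "MastCell",
                   "Treg", "GammaDeltaT")[seq_len(nCellTypes)]
  genes <- sprintf("G%05d", seq_len(nGenes))
  sigs <- lapply(seq_len(nCellTypes), function(i) {
    idx <- ((i - 1L) * genesPerSignature + 1L):(i * genesPerSignature)
    GeneSignature(cellTypes[i], genes[idx])
  })
  names(sigs) <- cellTypes
  sigs
}

#' Simulate paired whole-bone-marrow expression with planted immune structure
#'
#' Cell fractions are Dirichlet draws whose concentration is tilted both by
#' a planted cluster pattern (k distinct mean compositions) and by lambda
#' through per-cell-type coupling slopes (positive coupling: fraction rises
#' with malignancy). Expression is the fraction-weighted mixture of
#' cell-type archetypes — each archetype over-expresses its own signature
#' genes by a fixed shift — plus Gaussian noise.
#'
#' @param truth \linkS4class{SimTruth}.
#' @param cellSignatures named list of \linkS4class{GeneSignature} (disjoint
#'   marker sets define the archetypes).
#' @param coupling named numeric, slope of log-concentration on (lambda -
#'   0.5) per cell type; 0 for uncoupled types.
#' @param kPlanted number of planted clusters (default 1, i.e. none).
#' @param clusterSep log-scale separation of planted mean compositions
#'   (default 1.5).
#' @param concentration Dirichlet concentration scale; larger = tighter
#'   compositions (default 100).
#' @param archetypeShift log2 over-expression of a cell type's own markers
#'   (default 3).
#' @param noiseSd residual sd (default 0.3).
#' @param nGenes gene universe size (must cover all signatures).
#' @param seed integer seed.
#' @return list with \code{wbm} (genes x samples), \code{fractions}
#'   (samples x cell types), \code{clusters} (planted labels, integer),
#'   \code{coupling}.
#' @export
simulateWBM <- function(truth, cellSignatures, coupling = NULL,
                        kPlanted = 1L, clusterSep = 1.5,
                        concentration = 100, archetypeShift = 3,
                        noiseSd = 0.3, nGenes = 2000L, seed = 1L) {
  lam <- simLambda(truth)
  n <- length(lam)
  if (kPlanted < 1L || kPlanted > n) stop("invalid kPlanted")
  types <- names(cellSignatures)
  if (is.null(coupling)) coupling <- setNames(rep(0, length(types)), types)
  if (!all(types %in% names(coupling)))
    stop("coupling must be defined for every cell type")
  genes <- sprintf("G%05d", seq_len(nGenes))
  for (s in cellSignatures)
    if (!all(s@genes %in% genes)) stop("signature genes outside the universe")
  withr_seed(seed, {
    mu <- rnorm(nGenes, 6, 1)
    arch <- matrix(mu, nGenes, length(types),
                   dimnames = list(genes, types))
    for (ct in types)
      arch[cellSignatures[[ct]]@genes, ct] <-
        arch[cellSignatures[[ct]]@genes, ct] + archetypeShift
    clusterPattern <- matrix(rnorm(kPlanted * length(types)),
                             kPlanted, length(types))
    clusters <- sample(rep_len(seq_len(kPlanted), n))
    frac <- matrix(0, n, length(types),
                   dimnames = list(names(lam), types))
    for (i in seq_len(n)) {
      conc <- concentration * exp(clusterSep * clusterPattern[clusters[i], ] +
                                    coupling[types] * (lam[i] - 0.5))
      g <- rgamma(length(types), shape = conc, rate = 1)
      frac[i, ] <- g / sum(g)
    }
    wbm <- arch %*% t(frac) +
      matrix(rnorm(nGenes * n, 0, noiseSd), nGenes, n)
    colnames(wbm) <- names(lam)
    list(wbm = wbm, fractions = frac, clusters = setNames(clusters, names(lam)),
         coupling = coupling)
  })
}

#' Simulate an MGUS progression cohort
#'
#' Non-progressor scores are Normal(0, 1); progressor scores Normal(delta,
#' 1). The default sizes mirror an MGUS cohort with longitudinal follow-up
#' (358 patients, 39 progressors) and delta = 1.07 gives a closed-form
#' binormal AUC of Phi(delta / sqrt(2)) ~ 0.776.
#'
#' @param n cohort size (default 358).
#' @param nProgressors number that progress to MM (default 39).
#' @param delta score shift of progressors, sd units (default 1.07).
#' @param seed integer seed.
#' @return data.frame with sample_id, score, progressed.
#' @export
simulateProgressionCohort <- function(n = 358L, nProgressors = 39L,
                                      delta = 1.07, seed = 1L) {
  if (nProgressors >= n) stop("nProgressors must be < n")
  withr_seed(seed, {
    progressed <- c(rep(0L, n - nProgressors), rep(1L, nProgressors))
    score <- rnorm(n, mean = delta * progressed, sd = 1)
    data.frame(sample_id = sprintf("M%04d", seq_len(n)), score = score,
               progressed = progressed, stringsAsFactors = FALSE)
  })
}

#' Simulate a full evaluation cohort
#'
#' Bundles the generators into one cohort: expression with perturbed plasma
#' markers, lambda-driven survival, stage labels, an ISS stage drawn
#' independently of lambda (so the score carries prognostic signal the
#' staging system does not), and lambda-coupled mutations.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param beta log HR per unit lambda for survival (default log(1.72)).
#' @param issBeta log HR per ISS step, applied on top of the lambda effect.
#' @param censorFrac censoring fraction (default 0.3).
#' @param ... passed to \code{\link{simulateExpression}}.
#' @return list with expr, truth, signature, clinical (sample_id, os_time,
#'   os_event, iss, stage_label), mutations.
#' @export
simulateCohort <- function(n = 762L, seed = 1L, beta = log(1.72),
                           issBeta = 0.4, censorFrac = 0.3, ...) {
  sim <- simulateExpression(n, seed = seed, ...)
  lam <- simLambda(sim$truth)
  iss <- withr_seed(seed + 101L, sample(1:3, n, replace = TRUE))
  # hazard combines the independent ISS effect and the lambda effect
  rates <- 0.02 * exp(beta * lam + issBeta * (iss - 2))
  surv <- withr_seed(seed + 202L, {
    t <- rexp(n, rates)
    censProb <- function(u) mean((1 - exp(-rates * u)) / (rates * u))
    u <- uniroot(function(u) censProb(u) - censorFrac,
                 lower = 1e-6, upper = 1e8, tol = 1e-8)$root
    cens <- runif(n, 0, u)
    data.frame(os_time = pmin(t, cens), os_event = as.integer(t <= cens))
  })
  stages <- simulateStages(sim$truth)
  drivers <- data.frame(gene = c("TP53", "MUC16", "KRAS"),
                        intercept = c(-3, -2.5, -2), slope = c(3, 2.5, 1),
                        stringsAsFactors = FALSE)
  muts <- simulateMutations(sim$truth, drivers, seed = seed + 303L)
  clinical <- data.frame(sample_id = names(lam), os_time = surv$os_time,
                         os_event = surv$os_event, iss = iss,
                         stage_label = stages, stringsAsFactors = FALSE)
  list(expr = sim$expr, truth = sim$truth, signature = sim$signature,
       clinical = clinical, mutations = muts)
}
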