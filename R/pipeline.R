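# End-to-end orchestration: a validated config drives simulate -> score ->
# survival/stage/progression/mutation analyses and a JSON report bundle.
# Every stochastic step derives its seed from the config, so two runs with
# the same config produce numerically identical reports (timestamps are
# isolated in a metadata block).

.CONFIG_DEFAULTS <- list(
  preset = NULL,            # "commpass-like", "mgus-like" or NULL
  expression = NULL,        # TSV path (used when preset is NULL)
  gmt = NULL,               # GMT path
  clinical = NULL,          # clinical TSV path
  maf = NULL,               # MAF path (optional)
  plasma_signature = "PlasmaB",
  n_perm = 1000L,
  seed = 1L,
  endpoint = "os",          # "os" or "efs"
  n_samples = 400L,         # preset cohort size
  repeats = 20L,
  folds = 5L,
  min_carriers = 5L,
  k_clusters = 5L,
  alpha = 0.05,             # report-flagging level only, never a filter
  out_dir = NULL)

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a named list), rejects unknown keys with a
#' closest-match suggestion, fills defaults, and checks types and ranges.
#'
#' @param config path to a YAML file or a named list.
#' @return validated config list with defaults filled.
#' @export
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown)) {
    hint <- vapply(unknown, function(k) {
      d <- utils::adist(k, names(.CONFIG_DEFAULTS))
      best <- names(.CONFIG_DEFAULTS)[which.min(d)]
      if (min(d) <= 3L) sprintf(" (did you mean '%s'?)", best) else ""
    }, character(1))
    stop("unknown config key(s): ",
         paste0("'", unknown, "'", hint, collapse = ", "))
  }
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, config)
  if (!is.null(cfg$preset) &&
      !cfg$preset %in% c("commpass-like", "mgus-like"))
    stop("unknown preset: ", cfg$preset)
  if (cfg$n_perm < 100L) stop("n_perm must be >= 100")
  if (!cfg$endpoint %in% c("os", "efs")) stop("endpoint must be 'os' or 'efs'")
  cfg$seed <- as.integer(cfg$seed)
  for (p in c("expression", "gmt", "clinical", "maf"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop(sprintf("config path '%s' does not exist: %s", p, cfg[[p]]))
  if (is.null(cfg$preset) && is.null(cfg$expression))
    stop("either a preset or an expression path is required")
  cfg
}

#' Run the full evaluation pipeline
#'
#' Stages in dependency order: obtain inputs (simulate a preset cohort or
#' read the configured files), score signatures and derive the PBM score,
#' then — as the available clinical columns permit — median-split survival
#' (KM + log-rank + Cox), cross-validated staging-model comparison, stage
#' trend and discrimination, progression ROC, and mutation association.
#' Excluded samples are reported with counts and reasons, never dropped
#' silently.
#'
#' @param config validated config (see \code{\link{validateConfig}}); a
#'   path or raw list is accepted and validated first.
#' @return report list; written as JSON to \code{out_dir} when configured.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  report <- list(config = cfg[!vapply(cfg, is.null, TRUE)],
                 exclusions = list())
  if (!is.null(cfg$preset) && cfg$preset == "mgus-like") {
    cohort <- simulateProgressionCohort(seed = cfg$seed)
    prog <- progressionEval(cohort$score, cohort$progressed)
    report$progression <- list(
      auc = prog$roc$auc, cutoff = prog$cutoff$cutoff,
      sensitivity = prog$cutoff$sensitivity,
      specificity = prog$cutoff$specificity,
      rate_high = prog$rate_high, rate_low = prog$rate_low,
      rate_ratio = prog$rate_ratio, fisher_p = prog$fisher_p,
      table = as.vector(prog$table))
    return(.finishReport(report, cfg))
  }
  if (!is.null(cfg$preset)) {
    sim <- simulateCohort(n = cfg$n_samples, seed = cfg$seed)
    expr <- sim$expr; signatures <- list(PlasmaB = sim$signature)
    clinical <- sim$clinical; mutations <- sim$mutations
    plasma <- "PlasmaB"
  } else {
    expr <- readExpression(cfg$expression)
    signatures <- readGMT(cfg$gmt)
    clinical <- if (!is.null(cfg$clinical)) readClinical(cfg$clinical)
    mutations <- if (!is.null(cfg$maf)) readMAF(cfg$maf)
    plasma <- cfg$plasma_signature
  }
  scores <- scoreSignatures(expr, signatures, plasmaSignature = plasma,
                            nPerm = cfg$n_perm, seed = cfg$seed)
  pbm <- pbmScores(scores)
  report$scoring <- list(n_samples = length(pbm),
                         n_signatures = ncol(scoreMatrix(scores)),
                         pbm_mean = mean(pbm), pbm_sd = sd(pbm))
  if (is.null(clinical)) return(.finishReport(report, cfg))

  timeCol <- paste0(cfg$endpoint, "_time")
  eventCol <- paste0(cfg$endpoint, "_event")
  if (!all(c(timeCol, eventCol) %in% colnames(clinical))) {
    if (cfg$endpoint == "efs")
      stop("endpoint 'efs' requires columns efs_time and efs_event")
  } else {
    ids <- intersect(names(pbm), clinical$sample_id)
    m <- match(ids, clinical$sample_id)
    ok <- !is.na(clinical[[timeCol]][m]) & !is.na(clinical[[eventCol]][m])
    report$exclusions$survival <- list(
      n_excluded = sum(!ok), reason = "missing survival outcome")
    ids <- ids[ok]; m <- m[ok]
    grp <- medianSplit(pbm[ids])
    lr <- kmLogrank(clinical[[timeCol]][m], clinical[[eventCol]][m], grp)
    cox <- coxFit(clinical[[timeCol]][m], clinical[[eventCol]][m],
                  data.frame(pbm_high = as.integer(grp == "high")))
    report$survival <- list(
      n = length(ids), logrank_chisq = lr$chisq, logrank_p = lr$p_value,
      hr = cox$coefficients$hr[1L],
      hr_ci = c(cox$coefficients$ci_lower[1L],
                cox$coefficients$ci_upper[1L]),
      cox_p = cox$coefficients$p_value[1L],
      significant = lr$p_value < cfg$alpha)
    if ("iss" %in% colnames(clinical)) {
      cdat <- data.frame(clinical[m, c(timeCol, eventCol, "iss")],
                         pbm = pbm[ids], row.names = ids)
      cv <- cvCompareModels(cdat,
        list(iss = "iss", iss_pbm = c("iss", "pbm")),
        timeCol = timeCol, eventCol = eventCol,
        repeats = cfg$repeats, folds = cfg$folds, seed = cfg$seed)
      report$cv_models <- list(mean_c = as.list(cv$mean_c),
                               p_iss_vs_iss_pbm = cv$pairwise_p["iss",
                                                               "iss_pbm"])
    }
  }
  if ("stage_label" %in% colnames(clinical)) {
    ids <- intersect(names(pbm), clinical$sample_id)
    m <- match(ids, clinical$sample_id)
    st <- clinical$stage_label[m]
    if (length(unique(st[!is.na(st)])) >= 3L) {
      tr <- trendTest(pbm[ids][!is.na(st)], st[!is.na(st)])
      auc <- stageDiscrimination(pbm[ids][!is.na(st)], st[!is.na(st)])
      report$stages <- list(trend_statistic = tr$statistic,
                            trend_p = tr$p_value,
                            pairwise_auc = auc)
    }
  }
  if (!is.null(mutations) && nrow(mutations)) {
    tmb <- computeTMB(mutations, names(pbm))
    assoc <- tmbPbmAssociation(tmb, pbm)
    genes <- selectFrequentGenes(mutations, names(pbm),
                                 whitelist = unique(mutations$gene),
                                 minCarriers = cfg$min_carriers)
    mut <- mutationPbmAssociation(mutations, pbm, genes)
    report$mutations <- list(
      tmb_median = median(tmb), tmb_pbm_p = assoc$p_value,
      tmb_pbm_direction = assoc$direction,
      genes_tested = genes,
      per_gene = if (!is.null(mut)) mut)
  }
  .finishReport(report, cfg)
}

.finishReport <- function(report, cfg) {
  out <- report
  out$metadata <- list(package_version =
                         as.character(utils::packageVersion("pbmScore")),
                       timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(out, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  out
}
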