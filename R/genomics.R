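# Mutation-side analyses: tumour mutation burden, frequently mutated gene
# selection against a user-supplied whitelist, mutation-PBM association,
# and mutation-stratified survival with a global-median PBM split.

# standard MAF nonsynonymous vocabulary
NONSYNONYMOUS_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site")

KNOWN_CLASSES <- c(NONSYNONYMOUS_CLASSES, "Silent", "Intron", "IGR",
  "3'UTR", "5'UTR", "3'Flank", "5'Flank", "RNA", "lincRNA",
  "De_novo_Start_InFrame", "De_novo_Start_OutOfFrame",
  "Targeted_Region", "Nonsense", "Splice_Region")

#' Tumour mutation burden
#'
#' Counts each sample's nonsynonymous records (missense, nonsense, nonstop,
#' frameshift, in-frame indel, splice-site, translation-start). Samples
#' without records get 0. Unknown variant classifications are excluded with
#' a message (strict mode errors instead).
#'
#' @param mutations data.frame from \code{\link{readMAF}}.
#' @param samples character vector of all cohort samples.
#' @param strict error on unknown variant classifications.
#' @return named integer vector of TMB per sample.
#' @export
computeTMB <- function(mutations, samples, strict = FALSE) {
  unknown <- setdiff(unique(mutations$variant_classification), KNOWN_CLASSES)
  if (length(unknown)) {
    if (strict)
      stop("unknown variant classification(s): ",
           paste(unknown, collapse = ", "))
    message("excluding unknown variant classification(s): ",
            paste(unknown, collapse = ", "))
  }
  ns <- mutations[mutations$variant_classification %in% NONSYNONYMOUS_CLASSES, ]
  counts <- table(factor(ns$sample_id, levels = samples))
  setNames(as.integer(counts), samples)
}

# per-gene carrier sets (samples with >= 1 nonsynonymous record)
mutationCarriers <- function(mutations, samples) {
  ns <- mutations[mutations$variant_classification %in% NONSYNONYMOUS_CLASSES &
                    mutations$sample_id %in% samples, ]
  lapply(split(ns$sample_id, ns$gene), unique)
}

#' TMB-PBM association
#'
#' Splits the cohort at the median TMB (ties to low) and compares PBM
#' between TMB-high and TMB-low with the Wilcoxon rank-sum test.
#'
#' @param tmb named per-sample TMB.
#' @param pbm named per-sample PBM scores (same samples).
#' @return a group-comparison list (statistic, p_value, group_sizes,
#'   direction: positive when the TMB-high group has higher PBM).
#' @export
tmbPbmAssociation <- function(tmb, pbm) {
  ids <- intersect(names(tmb), names(pbm))
  if (length(ids) < 4L) stop("need >= 4 samples shared between TMB and PBM")
  grp <- medianSplit(tmb[ids])
  if (min(table(grp)) < 2L) stop("degenerate TMB split")
  wilcoxonRankSum(pbm[ids][grp == "high"], pbm[ids][grp == "low"],
                  mode = "normal-approx")
}

#' Select frequently mutated genes
#'
#' Whitelisted genes (e.g. a COSMIC Cancer Gene Census list supplied by the
#' user) with at least \code{minCarriers} carriers, ordered by carrier
#' count descending (ties by gene name), truncated to \code{topN}.
#'
#' @param mutations mutation data.frame.
#' @param samples cohort samples.
#' @param whitelist non-empty character vector of eligible genes.
#' @param minCarriers minimum carrier count (default 30).
#' @param topN maximum genes returned (default 10).
#' @return character vector of selected genes (possibly empty).
#' @export
selectFrequentGenes <- function(mutations, samples, whitelist,
                                minCarriers = 30L, topN = 10L) {
  if (!length(whitelist)) stop("whitelist must be non-empty")
  carriers <- mutationCarriers(mutations, samples)
  carriers <- carriers[names(carriers) %in% whitelist]
  counts <- vapply(carriers, length, 0L)
  counts <- counts[counts >= minCarriers]
  if (!length(counts)) return(character())
  ord <- order(-counts, names(counts))
  head(names(counts)[ord], topN)
}

#' Per-gene mutation-PBM association
#'
#' For each gene, Wilcoxon comparison of PBM between carriers and
#' wild-type samples, BH-adjusted across genes. Genes with fewer than 2
#' carriers or 2 wild-type samples are skipped with a message.
#'
#' @param mutations mutation data.frame.
#' @param pbm named per-sample PBM scores (defines the cohort).
#' @param genes genes to test.
#' @return data.frame: gene, n_carrier, n_wildtype, p_value, p_adjusted,
#'   direction (positive = carriers have higher PBM).
#' @export
mutationPbmAssociation <- function(mutations, pbm, genes) {
  samples <- names(pbm)
  carriers <- mutationCarriers(mutations, samples)
  rows <- lapply(genes, function(g) {
    carr <- intersect(carriers[[g]], samples)
    wt <- setdiff(samples, carr)
    if (length(carr) < 2L || length(wt) < 2L) {
      message(sprintf("gene %s skipped: %d carrier(s), %d wild-type",
                      g, length(carr), length(wt)))
      return(NULL)
    }
    res <- wilcoxonRankSum(pbm[carr], pbm[wt], mode = "normal-approx")
    data.frame(gene = g, n_carrier = length(carr), n_wildtype = length(wt),
               p_value = res$p_value, direction = res$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_adjusted <- bhAdjust(out$p_value)
  out[, c("gene", "n_carrier", "n_wildtype", "p_value", "p_adjusted",
          "direction")]
}

#' Mutation-stratified survival of the PBM median split
#'
#' Splits PBM at the GLOBAL median (all patients, not per stratum), then
#' runs KM + log-rank and a univariable Cox fit of the high/low indicator
#' within the mutated and wild-type strata separately. Strata that are
#' empty or event-free are omitted with a message.
#'
#' @param mutations mutation data.frame.
#' @param pbm named per-sample PBM scores.
#' @param clinical data.frame with sample_id, os_time, os_event.
#' @param gene the stratifying gene.
#' @return named list (mutated, wild_type), each with \code{n},
#'   \code{logrank}, and \code{cox} (NULL when the stratum was unusable).
#' @export
stratifiedSurvival <- function(mutations, pbm, clinical, gene) {
  samples <- intersect(names(pbm), clinical$sample_id)
  grp <- medianSplit(pbm[samples])     # global median split
  carr <- intersect(mutationCarriers(mutations, samples)[[gene]], samples)
  strata <- list(mutated = carr, wild_type = setdiff(samples, carr))
  m <- match(samples, clinical$sample_id)
  times <- setNames(clinical$os_time[m], samples)
  events <- setNames(clinical$os_event[m], samples)
  out <- lapply(names(strata), function(st) {
    ids <- strata[[st]]
    if (length(ids) < 4L || sum(events[ids]) == 0 ||
        length(unique(grp[ids])) < 2L) {
      message(sprintf("stratum '%s' omitted (n = %d)", st, length(ids)))
      return(NULL)
    }
    g <- droplevels(grp[ids])
    lr <- kmLogrank(times[ids], events[ids], g)
    cox <- coxFit(times[ids], events[ids],
                  data.frame(pbm_high = as.integer(g == "high")))
    list(n = length(ids), logrank = lr, cox = cox)
  })
  names(out) <- names(strata)
  out[!vapply(out, is.null, TRUE)]
}
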