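# Tumour immune microenvironment (TIME) profiling of whole-bone-marrow
# expression: per-cell-type signature scores, the exclusion/abundance
# filter, mean-0/sd-1 normalization, Ward clustering into k immune
# clusters, and the cluster/PBM/survival association report.

#' Score immune cell-type signatures on whole-bone-marrow profiles
#'
#' Runs the single-sample signature-score engine over every cell-type
#' signature, yielding one column per cell type.
#'
#' @param wbm genes x samples whole-bone-marrow expression matrix.
#' @param signatures named list of \linkS4class{GeneSignature}.
#' @inheritParams scoreSignature
#' @return samples x cell-types numeric matrix of signature z-scores.
#' @export
estimateTIME <- function(wbm, signatures, nPerm = 1000L, seed = 1L,
                         minGenes = 5L) {
  sc <- scoreSignatures(wbm, signatures, plasmaSignature = NULL,
                        nPerm = nPerm, seed = seed, minGenes = minGenes)
  scoreMatrix(sc)
}

#' Filter cell types before clustering
#'
#' Drops explicitly named cell types (e.g. osteoblast, osteoclast,
#' adipocyte) always, and — when the input is on a fraction scale — cell
#' types whose cross-sample mean falls below \code{minMeanFraction}
#' (default 1\%). The abundance filter refuses score-scale input: fractions
#' must be non-negative with per-sample sums at most 1.
#'
#' @param mat samples x cell-types matrix (signature scores, or fractions
#'   for the abundance filter).
#' @param excludeNames cell-type names to drop unconditionally.
#' @param minMeanFraction mean-fraction threshold, or \code{NULL} to skip
#'   the abundance filter.
#' @return filtered matrix; attribute \code{excluded} records what was
#'   dropped and why.
#' @export
filterCellTypes <- function(mat, excludeNames = character(),
                            minMeanFraction = NULL) {
  if (!is.matrix(mat) || ncol(mat) == 0L) stop("empty cell-type matrix")
  excluded <- data.frame(cell_type = character(), reason = character(),
                         stringsAsFactors = FALSE)
  drop <- intersect(excludeNames, colnames(mat))
  if (length(drop))
    excluded <- rbind(excluded, data.frame(cell_type = drop,
                                           reason = "named exclusion"))
  keep <- setdiff(colnames(mat), drop)
  m <- mat[, keep, drop = FALSE]
  if (!is.null(minMeanFraction)) {
    if (any(m < 0) || any(rowSums(m) > 1 + 1e-6))
      stop("abundance filter needs fraction-scale input (non-negative, row sums <= 1)")
    low <- colnames(m)[colMeans(m) < minMeanFraction]
    if (length(low))
      excluded <- rbind(excluded, data.frame(
        cell_type = low,
        reason = sprintf("mean fraction < %g", minMeanFraction)))
    m <- m[, setdiff(colnames(m), low), drop = FALSE]
  }
  if (ncol(m) == 0L) stop("all cell types excluded")
  attr(m, "excluded") <- excluded
  m
}

#' Standardize cell-type columns to mean 0, sd 1
#'
#' Per-cell-type z-normalization with the sample standard deviation
#' (denominator n - 1). Idempotent to numerical precision.
#'
#' @param mat samples x cell-types matrix; every column must vary.
#' @return matrix of the same shape with columns standardized.
#' @export
zNormalize <- function(mat) {
  sds <- apply(mat, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance cell type(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  out <- scale(mat)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Cluster samples into immune-microenvironment clusters
#'
#' Agglomerative clustering with Ward linkage (ward.D2) on Euclidean
#' distances, cut at k clusters; labels C1..Ck are assigned by decreasing
#' cluster size (ties broken by first occurrence), making the labelling
#' deterministic and outcome-blind.
#'
#' @param mat samples x cell-types matrix (normally z-normalized).
#' @param k number of clusters (default 5).
#' @return factor of cluster labels C1..Ck, named by sample.
#' @export
clusterTIME <- function(mat, k = 5L) {
  if (nrow(mat) < k) stop("fewer samples than clusters")
  hc <- hclust(dist(mat), method = "ward.D2")
  raw <- cutree(hc, k = k)
  sizes <- table(raw)
  ord <- order(-as.vector(sizes), as.integer(names(sizes)))
  relabel <- setNames(paste0("C", seq_len(k)), names(sizes)[ord])
  f <- factor(relabel[as.character(raw)], levels = paste0("C", seq_len(k)))
  names(f) <- rownames(mat)
  f
}

#' Associate TIME clusters with PBM score and survival
#'
#' Per-cluster PBM summaries; Wilcoxon comparison of every cluster against
#' the highest-mean-PBM cluster; log-rank across clusters (when survival is
#' supplied); and per-cell-type Wilcoxon between high- and low-PBM sample
#' groups (median split). Comparisons involving singleton clusters are
#' reported with a note rather than failing.
#'
#' @param clusters factor of cluster labels, named by sample.
#' @param pbm named per-sample PBM scores.
#' @param clinical optional data.frame with sample_id, os_time, os_event.
#' @param cellTypeMatrix optional samples x cell-types matrix for the
#'   high-vs-low PBM infiltration comparison.
#' @return list with \code{cluster_summary}, \code{vs_top_cluster},
#'   \code{logrank}, \code{celltype_vs_pbm}, \code{notes}.
#' @export
clusterAssociations <- function(clusters, pbm, clinical = NULL,
                                cellTypeMatrix = NULL) {
  ids <- names(clusters)
  if (is.null(ids) || is.null(names(pbm)) || !all(ids %in% names(pbm)))
    stop("cluster and PBM sample identifiers are misaligned")
  pbm <- pbm[ids]
  notes <- character()
  summary <- data.frame(
    cluster = levels(clusters),
    n = as.vector(table(clusters)),
    mean_pbm = as.vector(tapply(pbm, clusters, mean)),
    median_pbm = as.vector(tapply(pbm, clusters, median)))
  top <- summary$cluster[which.max(summary$mean_pbm)]
  vs <- lapply(setdiff(levels(clusters), top), function(cl) {
    x <- pbm[clusters == cl]; y <- pbm[clusters == top]
    if (length(x) < 2L || length(y) < 2L) {
      notes <<- c(notes, sprintf(
        "comparison %s vs %s unstable: singleton cluster", cl, top))
    }
    res <- wilcoxonRankSum(x, y, mode = "normal-approx")
    data.frame(cluster = cl, vs = top, p_value = res$p_value,
               direction = res$direction)
  })
  vs <- do.call(rbind, vs)
  logrank <- NULL
  if (!is.null(clinical)) {
    m <- match(ids, clinical$sample_id)
    if (anyNA(m)) stop("clinical sample identifiers are misaligned")
    logrank <- kmLogrank(clinical$os_time[m], clinical$os_event[m], clusters)
  }
  ctp <- NULL
  if (!is.null(cellTypeMatrix)) {
    if (!all(ids %in% rownames(cellTypeMatrix)))
      stop("cell-type matrix sample identifiers are misaligned")
    ctm <- cellTypeMatrix[ids, , drop = FALSE]
    grp <- medianSplit(pbm)
    ctp <- do.call(rbind, lapply(colnames(ctm), function(ct) {
      res <- wilcoxonRankSum(ctm[grp == "high", ct], ctm[grp == "low", ct],
                             mode = "normal-approx")
      data.frame(cell_type = ct, p_value = res$p_value,
                 direction = res$direction)
    }))
    ctp$p_adjusted <- bhAdjust(ctp$p_value)
  }
  list(cluster_summary = summary, vs_top_cluster = vs, logrank = logrank,
       celltype_vs_pbm = ctp, notes = notes)
}
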