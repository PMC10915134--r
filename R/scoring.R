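# The single-sample rank-based scoring engine.
#
# For one sample, genes are ranked by expression (descending). A signed
# Kolmogorov-Smirnov-type running-sum statistic measures how far the
# signature genes sit from a uniform scatter across that ranking:
# F(i) = (weighted) fraction of signature genes seen by rank i, B(i) =
# fraction of background genes seen; ES = F(i*) - B(i*) at the position i*
# of maximal |F - B| (earliest on ties). ES is normalized to a z-score
# against a null of uniformly random signature placements, which depends
# only on the universe and signature sizes and is therefore shared across
# samples of the same matrix. The PBM score is the sign-flipped z of the
# plasma-cell signature, so that depressed plasma markers (bottom ranks,
# negative ES) give a high, "more malignant" score.

#' Rank the genes of one sample
#'
#' Orders genes by expression, descending; ties are broken by ascending
#' lexicographic gene identifier (C locale), making the ranking fully
#' deterministic.
#'
#' @param values finite numeric expression values of one sample.
#' @param geneIds gene identifiers, same length as \code{values}.
#' @return character vector of gene identifiers, highest expression first.
#' @examples
#' rankSample(c(5, 1, 3), c("A", "B", "C"))
#' @export
rankSample <- function(values, geneIds) {
  if (length(values) < 2L) stop("need >= 2 genes to rank")
  if (length(values) != length(geneIds))
    stop("values and geneIds lengths differ")
  if (!all(is.finite(values))) stop("non-finite expression value")
  geneIds[order(-values, geneIds, method = "radix")]
}

#' Signed running-sum enrichment statistic
#'
#' Walks the ranking and returns \code{F(i*) - B(i*)} at the position of
#' maximal absolute difference between the cumulative signature fraction F
#' and cumulative background fraction B (earliest position on ties). The
#' statistic lies in [-1, 1]: +1 when the signature occupies the top ranks
#' exactly, -1 when it occupies the bottom.
#'
#' @param order ranked gene identifiers (from \code{\link{rankSample}}).
#' @param signature a \linkS4class{GeneSignature} or character vector of
#'   genes; must intersect the universe but not cover it.
#' @param weights optional non-negative per-position foreground weights
#'   (same length/order as \code{order}); used by the weighted variant
#'   (\code{weightExponent > 0} in \code{\link{scoreSignature}}). Positions
#'   outside the signature are ignored. \code{NULL} means uniform weights.
#' @return the enrichment statistic, a single number in [-1, 1].
#' @examples
#' enrichmentStatistic(c("g1", "g2", "g3", "g4"), c("g1", "g3"))  # 0.5
#' @export
enrichmentStatistic <- function(order, signature, weights = NULL) {
  genes <- if (is(signature, "GeneSignature")) signature@genes else signature
  member <- order %in% genes
  m <- sum(member)
  n <- length(order)
  if (m == 0L) stop("signature does not intersect the universe")
  if (m == n) stop("signature equals the universe; background undefined")
  if (is.null(weights)) {
    # integer numerator of F - B over the common denominator m * (n - m):
    # exact arithmetic makes the maximum and its tie-break deterministic
    h <- cumsum(member)
    i <- seq_len(n)
    num <- h * (n - m) - (i - h) * m
    j <- which.max(abs(num))   # earliest position of the maximal |F - B|
    return(num[j] / (m * (n - m)))
  }
  if (length(weights) != n) stop("weights length must match order")
  w <- ifelse(member, weights, 0)
  tw <- sum(w)
  if (tw <= 0) stop("all foreground weights are zero")
  d <- cumsum(w) / tw - cumsum(!member) / (n - m)
  i <- which.max(abs(d))
  d[i]
}

# enrichment statistic for a placement given as sorted signature positions;
# O(m) via the piecewise-linear structure: candidate extrema sit at hit
# positions (local maxima of F-B) and just before the next hit (local
# minima). Used by the permutation null.
.esFromPositions <- function(pos, n) {
  m <- length(pos)
  j <- seq_len(m)
  # integer numerators over the denominator m * (n - m)
  numHit <- j * (n - m) - (pos - j) * m            # value at each hit
  preIdx <- pos - 1L                               # position before each hit
  numPre <- (j - 1L) * (n - m) - (preIdx - (j - 1L)) * m
  cand <- c(rbind(numPre, numHit))
  candPos <- c(rbind(preIdx, pos))
  keep <- candPos >= 1L
  cand <- cand[keep]; candPos <- candPos[keep]
  a <- abs(cand)
  best <- which(a == max(a))
  cand[best[which.min(candPos[best])]] / (m * (n - m))
}

#' Permutation-normalize an enrichment statistic
#'
#' Builds the null distribution of the statistic by placing the signature
#' uniformly at random (without replacement) in a ranking of the same size,
#' and returns \code{z = (es - mean_null) / sd_null}. The null depends only
#' on the universe and signature sizes, never on the expression values. When
#' \code{choose(orderSize, signatureSize) <= exhaustiveLimit} every placement
#' is enumerated instead of sampled. The null sd is the population
#' (divide-by-N) standard deviation of the null draws.
#'
#' @param esRaw observed enrichment statistic.
#' @param orderSize number of genes in the universe.
#' @param signatureSize number of signature genes in the universe.
#' @param nPerm Monte-Carlo permutations (>= 100).
#' @param seed integer seed for the Monte-Carlo null.
#' @param exhaustiveLimit enumerate all placements when the number of
#'   placements is at most this (default 10000).
#' @param null optional precomputed null vector (internal reuse across
#'   samples scored against the same universe).
#' @return list with \code{es_raw}, \code{z}, \code{n_perm} (number of null
#'   draws), \code{n_signature_in_universe}, and \code{exhaustive} flag.
#' @export
permutationNormalize <- function(esRaw, orderSize, signatureSize,
                                 nPerm = 1000L, seed = 1L,
                                 exhaustiveLimit = 10000L, null = NULL) {
  if (is.null(null))
    null <- enrichmentNull(orderSize, signatureSize, nPerm, seed,
                           exhaustiveLimit)
  mu <- mean(null)
  sdev <- sqrt(mean((null - mu)^2))
  if (sdev == 0) stop("degenerate null: sd is zero")
  list(es_raw = esRaw, z = (esRaw - mu) / sdev, n_perm = length(null),
       n_signature_in_universe = signatureSize,
       exhaustive = isTRUE(attr(null, "exhaustive")))
}

#' Null distribution of the enrichment statistic
#'
#' @inheritParams permutationNormalize
#' @return numeric vector of null enrichment statistics; attribute
#'   \code{exhaustive} records whether all placements were enumerated.
#' @export
enrichmentNull <- function(orderSize, signatureSize, nPerm = 1000L,
                           seed = 1L, exhaustiveLimit = 10000L) {
  n <- as.integer(orderSize); m <- as.integer(signatureSize)
  if (m < 1L || m >= n) stop("need 1 <= signatureSize < orderSize")
  nComb <- choose(n, m)
  if (nComb <= exhaustiveLimit) {
    placements <- combn(n, m)
    null <- apply(placements, 2L, .esFromPositions, n = n)
    attr(null, "exhaustive") <- TRUE
  } else {
    if (nPerm < 100L) stop("Monte-Carlo mode needs nPerm >= 100")
    null <- withr_seed(seed, {
      vapply(seq_len(nPerm),
             function(i) .esFromPositions(sort(sample.int(n, m)), n),
             numeric(1))
    })
    attr(null, "exhaustive") <- FALSE
  }
  null
}

# evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Score one signature across all samples of an expression matrix
#'
#' Applies rank -> running-sum statistic -> permutation z independently per
#' sample. Signature genes absent from the matrix are dropped with a message;
#' scoring requires at least \code{minGenes} remaining.
#'
#' @param exprMatrix numeric matrix, genes x samples (log scale).
#' @param signature a \linkS4class{GeneSignature}.
#' @param nPerm Monte-Carlo permutations for the null.
#' @param seed integer seed.
#' @param weightExponent alpha >= 0; when positive, the foreground running
#'   sum weights each signature gene by |expression - sample median|^alpha.
#'   Default 0 (unweighted).
#' @param minGenes minimum signature genes that must be present (default 5;
#'   relaxed automatically for universes too small to hold 5).
#' @return named numeric vector of per-sample z-scores.
#' @export
scoreSignature <- function(exprMatrix, signature, nPerm = 1000L, seed = 1L,
                           weightExponent = 0, minGenes = 5L) {
  validateExpression(exprMatrix)
  genes <- if (is(signature, "GeneSignature")) signature@genes else signature
  name <- if (is(signature, "GeneSignature")) signature@name else "signature"
  present <- intersect(genes, rownames(exprMatrix))
  dropped <- length(genes) - length(present)
  if (dropped > 0L)
    message(sprintf("signature '%s': %d gene(s) absent from matrix, dropped",
                    name, dropped))
  if (length(present) == 0L)
    stop(sprintf("signature '%s' has no genes in the matrix", name))
  minGenes <- min(minGenes, nrow(exprMatrix) - 1L)
  if (length(present) < minGenes)
    stop(sprintf("signature '%s': only %d gene(s) present (< %d required)",
                 name, length(present), minGenes))
  if (length(present) >= nrow(exprMatrix))
    stop(sprintf("signature '%s' covers the whole universe", name))
  n <- nrow(exprMatrix); m <- length(present)
  null <- enrichmentNull(n, m, nPerm, seed)
  mu <- mean(null)
  sdev <- sqrt(mean((null - mu)^2))
  if (sdev == 0) stop("degenerate null: sd is zero")
  ids <- rownames(exprMatrix)
  z <- vapply(seq_len(ncol(exprMatrix)), function(j) {
    v <- exprMatrix[, j]
    ord <- order(-v, ids, method = "radix")
    ranking <- ids[ord]
    w <- if (weightExponent > 0)
      abs(v[ord] - median(v))^weightExponent else NULL
    (enrichmentStatistic(ranking, present, weights = w) - mu) / sdev
  }, numeric(1))
  setNames(z, colnames(exprMatrix))
}

#' Score many signatures and derive the PBM score
#'
#' Convenience wrapper: scores every signature, then (when a plasma-cell
#' signature is designated) derives the per-sample PBM score via
#' \code{\link{computePBM}}.
#'
#' @param exprMatrix genes x samples matrix.
#' @param signatures named list of \linkS4class{GeneSignature}.
#' @param plasmaSignature name of the plasma-cell signature, or \code{NULL}.
#' @inheritParams scoreSignature
#' @param flipSign if \code{TRUE} (default) PBM = -z of the plasma signature,
#'   so higher = more perturbed = more malignant.
#' @return a \linkS4class{SignatureScores}.
#' @export
scoreSignatures <- function(exprMatrix, signatures, plasmaSignature = NULL,
                            nPerm = 1000L, seed = 1L, weightExponent = 0,
                            minGenes = 5L, flipSign = TRUE) {
  if (is(signatures, "GeneSignature")) signatures <- list(signatures)
  if (is.null(names(signatures)))
    names(signatures) <- vapply(signatures, function(s) s@name, character(1))
  z <- vapply(signatures, function(sig)
    scoreSignature(exprMatrix, sig, nPerm = nPerm, seed = seed,
                   weightExponent = weightExponent, minGenes = minGenes),
    numeric(ncol(exprMatrix)))
  if (ncol(exprMatrix) == 1L) z <- matrix(z, nrow = 1L,
    dimnames = list(colnames(exprMatrix), names(signatures)))
  computePBM(z, plasmaSignature, flipSign = flipSign)
}

#' Assemble a SignatureScores table and derive the PBM score
#'
#' The PBM score is the sign-flipped plasma-signature z-score (configurable),
#' so that stronger depression of plasma-cell markers — markers drifting to
#' the bottom of the within-sample ranking — yields a higher score.
#'
#' @param zMatrix samples x signatures matrix of normalized scores.
#' @param plasmaSignature column name of the plasma-cell signature, or
#'   \code{NULL} for a table without a PBM designation.
#' @param flipSign flip the sign (default \code{TRUE}).
#' @return a \linkS4class{SignatureScores}.
#' @export
computePBM <- function(zMatrix, plasmaSignature = NULL, flipSign = TRUE) {
  if (!is.null(plasmaSignature)) {
    if (!plasmaSignature %in% colnames(zMatrix))
      stop(sprintf("plasma signature '%s' not among score columns",
                   plasmaSignature))
    pbm <- if (flipSign) -zMatrix[, plasmaSignature]
           else zMatrix[, plasmaSignature]
    new("SignatureScores", scores = zMatrix, pbm = unname(pbm),
        plasmaSignature = plasmaSignature)
  } else {
    new("SignatureScores", scores = zMatrix, pbm = numeric(),
        plasmaSignature = character())
  }
}
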