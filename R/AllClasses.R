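#' @import methods
#' @importFrom stats median sd cor quantile pnorm pchisq phyper p.adjust
#'   rnorm runif rbinom rpois rexp rgamma setNames complete.cases
#'   wilcox.test fisher.test cor.test hclust cutree dist uniroot aggregate
#' @importFrom utils head read.delim write.table combn
NULL

#' GeneSignature: a named marker-gene set
#'
#' A cell-type (or pathway) label together with the unique gene identifiers
#' that mark it. Signatures are the unit consumed by the rank-based
#' single-sample scoring engine.
#'
#' @slot name single non-empty character, the cell-type label.
#' @slot genes character vector of unique, non-empty gene identifiers.
#' @export
setClass("GeneSignature",
  representation(name = "character", genes = "character"))

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@genes) == 0L)
    msg <- c(msg, "'genes' must be non-empty")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "'genes' must be unique within a signature")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSignature
#'
#' @param name cell-type label.
#' @param genes character vector of gene identifiers; duplicates are
#'   collapsed with a warning, surrounding whitespace is trimmed.
#' @return a \linkS4class{GeneSignature}.
#' @examples
#' GeneSignature("PlasmaB", c("SDC1", "XBP1", "PRDM1"))
#' @export
GeneSignature <- function(name, genes) {
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (anyDuplicated(genes)) {
    warning(sprintf("signature '%s': %d duplicate gene(s) collapsed",
                    name, sum(duplicated(genes))))
    genes <- unique(genes)
  }
  new("GeneSignature", name = as.character(name), genes = genes)
}

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature '%s' with %d genes\n",
              object@name, length(object@genes)))
  cat("  ", paste(head(object@genes, 8L), collapse = ", "),
      if (length(object@genes) > 8L) ", ..." else "", "\n", sep = "")
})

#' SignatureScores: per-sample normalized signature scores
#'
#' Holds the permutation-normalized enrichment z-score of every signature in
#' every sample, and (when a plasma-cell signature is designated) the derived
#' PBM score, oriented so that higher means more perturbed marker expression,
#' i.e. more malignant.
#'
#' @slot scores numeric matrix, samples x signatures, all finite.
#' @slot pbm numeric vector of per-sample PBM scores (length 0 when no plasma
#'   signature was designated).
#' @slot plasmaSignature character, name of the designated plasma signature
#'   (length 0 when none).
#' @export
setClass("SignatureScores",
  representation(scores = "matrix", pbm = "numeric",
                 plasmaSignature = "character"))

setValidity("SignatureScores", function(object) {
  msg <- character()
  s <- object@scores
  if (!is.numeric(s) || is.null(rownames(s)) || is.null(colnames(s)))
    msg <- c(msg, "'scores' must be a numeric matrix with dimnames")
  else {
    if (anyDuplicated(rownames(s)) || anyDuplicated(colnames(s)))
      msg <- c(msg, "duplicate sample or signature names")
    if (!all(is.finite(s)))
      msg <- c(msg, "all scores must be finite")
  }
  if (length(object@plasmaSignature) > 1L)
    msg <- c(msg, "'plasmaSignature' must have length 0 or 1")
  if (length(object@plasmaSignature) == 1L) {
    if (!object@plasmaSignature %in% colnames(s))
      msg <- c(msg, "plasma signature not among score columns")
    if (length(object@pbm) != nrow(s))
      msg <- c(msg, "'pbm' must have one value per sample")
  } else if (length(object@pbm) != 0L) {
    msg <- c(msg, "'pbm' present without a designated plasma signature")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SignatureScores", function(object) {
  cat(sprintf("SignatureScores: %d samples x %d signatures\n",
              nrow(object@scores), ncol(object@scores)))
  if (length(object@plasmaSignature)) {
    cat(sprintf("  plasma signature: '%s' (PBM = -z)\n",
                object@plasmaSignature))
    cat(sprintf("  PBM range: [%.3f, %.3f]\n",
                min(object@pbm), max(object@pbm)))
  }
})

#' @describeIn SignatureScores-accessors score matrix (samples x signatures)
#' @export
scoreMatrix <- function(x) x@scores

#' Accessors for SignatureScores
#'
#' @param x a \linkS4class{SignatureScores}.
#' @return \code{scoreMatrix}: the samples x signatures z-score matrix;
#'   \code{pbmScores}: the named per-sample PBM vector;
#'   \code{sampleNames}: the sample identifiers.
#' @name SignatureScores-accessors
#' @export
pbmScores <- function(x) {
  if (!length(x@plasmaSignature))
    stop("no plasma signature designated; PBM scores unavailable")
  setNames(x@pbm, rownames(x@scores))
}

#' @describeIn SignatureScores-accessors sample identifiers
#' @export
sampleNames <- function(x) rownames(x@scores)

#' SimTruth: ground truth of a simulated cohort
#'
#' Records the latent per-sample malignancy level and every generator
#' parameter, so that parameter-recovery tests can compare estimates with
#' known truth.
#'
#' @slot lambda numeric in [0,1], latent malignancy per sample (named).
#' @slot params named list of generator parameters (all finite scalars or
#'   vectors).
#' @slot seed integer seed the cohort was generated from.
#' @export
setClass("SimTruth",
  representation(lambda = "numeric", params = "list", seed = "integer"))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (any(object@lambda < 0 | object@lambda > 1))
    msg <- c(msg, "lambda must lie in [0,1]")
  if (is.null(names(object@lambda)))
    msg <- c(msg, "lambda must be named by sample")
  if (length(object@seed) != 1L)
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d samples, seed %d\n",
              length(object@lambda), object@seed))
  cat(sprintf("  lambda: mean %.3f, range [%.3f, %.3f]\n",
              mean(object@lambda), min(object@lambda), max(object@lambda)))
})

#' @describeIn SimTruth latent malignancy vector, named by sample
#' @param x a \linkS4class{SimTruth}.
#' @export
simLambda <- function(x) x@lambda

#' @describeIn SimTruth generator parameter list
#' @export
simParams <- function(x) x@params
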