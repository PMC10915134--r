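# Generic statistical kernel: rank tests, trend test, Fisher's exact test,
# BH adjustment, gene-score correlation, hypergeometric gene-set test.
# Group comparisons return a common result shape: statistic, p_value,
# group_sizes, direction (sign of the median difference).

#' Wilcoxon rank-sum comparison of two groups
#'
#' Exact mode enumerates all arrangements (requires total n <= 20 and no
#' ties); the normal approximation uses mid-ranks with tie correction and
#' continuity correction.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param mode "exact", "normal-approx", or "auto" (exact when feasible).
#' @return list with \code{statistic} (rank-sum W of x), \code{p_value}
#'   (two-sided), \code{group_sizes}, \code{direction} = sign(median(x) -
#'   median(y)).
#' @export
wilcoxonRankSum <- function(x, y, mode = c("auto", "exact", "normal-approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  n <- length(x) + length(y)
  if (mode == "exact" && (ties || n > 20L))
    stop("exact mode requires total n <= 20 and no ties")
  exact <- switch(mode, exact = TRUE, `normal-approx` = FALSE,
                  auto = !ties && n <= 20L)
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1  # identical groups under the approximation
  list(statistic = unname(wt$statistic),
       p_value = min(p, 1),
       group_sizes = c(length(x), length(y)),
       direction = sign(median(x) - median(y)))
}

#' Rank-based test for trend across ordered groups
#'
#' Cuzick-type Wilcoxon extension: with equally spaced group scores
#' l = 1..G, the statistic is T = sum over samples of l_i * R_i where R are
#' mid-ranks of the pooled values. The normal approximation uses the
#' tie-corrected variance; an exact permutation p (over all assignments of
#' values to the fixed group sizes) is available for total n <= 8.
#'
#' @param values numeric vector.
#' @param groups ordered factor (or coercible) with >= 3 levels present.
#' @param mode "normal-approx" (default), "exact" (n <= 8), or "auto".
#' @param alternative "two.sided" (default), "greater" (increasing trend) or
#'   "less".
#' @return list with \code{statistic} (standardized z for the approximation;
#'   raw T for exact mode), \code{p_value}, \code{group_sizes},
#'   \code{direction}.
#' @export
trendTest <- function(values, groups,
                      mode = c("normal-approx", "exact", "auto"),
                      alternative = c("two.sided", "greater", "less")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  groups <- if (is.factor(groups)) droplevels(groups)
            else factor(groups)
  if (nlevels(groups) < 3L)
    stop("trend test needs >= 3 ordered groups; use wilcoxonRankSum for 2")
  if (any(table(groups) == 0L)) stop("every group must be non-empty")
  if (length(values) != length(groups)) stop("length mismatch")
  n <- length(values)
  l <- as.integer(groups)                  # equally spaced scores 1..G
  r <- rank(values)                        # mid-ranks
  T <- sum(l * r)
  ng <- as.vector(table(groups))
  zg <- seq_len(nlevels(groups))
  ET <- (n + 1) / 2 * sum(ng * zg)
  if (mode == "auto") mode <- if (n <= 8L) "exact" else "normal-approx"
  if (mode == "exact") {
    if (n > 8L) stop("exact mode requires total n <= 8")
    perms <- .permutations(n)
    Tnull <- apply(perms, 1L, function(idx) sum(l * r[idx]))
    p <- switch(alternative,
      greater = mean(Tnull >= T),
      less = mean(Tnull <= T),
      two.sided = mean(abs(Tnull - ET) >= abs(T - ET) - 1e-12))
    stat <- T
  } else {
    tieTab <- table(r)
    tieCorr <- 1 - sum(tieTab^3 - tieTab) / (n^3 - n)
    VT <- (n + 1) / 12 * (n * sum(ng * zg^2) - sum(ng * zg)^2) * tieCorr
    if (VT <= 0) {
      stat <- 0; p <- 1
    } else {
      stat <- (T - ET) / sqrt(VT)
      p <- switch(alternative,
        greater = pnorm(stat, lower.tail = FALSE),
        less = pnorm(stat),
        two.sided = 2 * pnorm(-abs(stat)))
    }
  }
  medians <- tapply(values, groups, median)
  list(statistic = unname(stat), p_value = min(p, 1), group_sizes = ng,
       direction = sign(unname(medians[length(medians)] - medians[1L])))
}

# all permutations of 1..n as a matrix (rows); n small
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the minimum-likelihood convention: the sum of
#' hypergeometric probabilities of all tables with the observed margins that
#' are no more probable than the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts; both margins must
#'   be positive.
#' @return list with \code{statistic} (the odds-ratio estimate),
#'   \code{p_value}, \code{group_sizes} (row sums), \code{direction}
#'   (sign of log odds ratio).
#' @export
fisherExactTest <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("both margins must be positive")
  ft <- fisher.test(tab)
  lor <- log(tab[1, 1] + 0.5) + log(tab[2, 2] + 0.5) -
         log(tab[1, 2] + 0.5) - log(tab[2, 1] + 0.5)
  list(statistic = unname(ft$estimate), p_value = ft$p.value,
       group_sizes = rowSums(tab), direction = sign(lor))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, clipped at 1, returned in the input order.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed, passed
#'   through).
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Correlate every gene with a per-sample score
#'
#' @param exprMatrix genes x samples matrix.
#' @param score named per-sample vector; names must match the matrix columns
#'   (order-insensitive).
#' @param method "spearman" (default) or "pearson".
#' @return data.frame with one row per gene: \code{gene}, \code{cor},
#'   \code{p_value}, \code{p_adjusted} (BH). Constant genes get cor 0 and
#'   p 1, with a message.
#' @export
correlateGenesWithScore <- function(exprMatrix, score,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  validateExpression(exprMatrix)
  if (ncol(exprMatrix) < 3L) stop("need >= 3 samples")
  if (is.null(names(score)) || !setequal(names(score), colnames(exprMatrix)))
    stop("score names must match the matrix sample identifiers")
  score <- score[colnames(exprMatrix)]
  res <- t(apply(exprMatrix, 1L, function(v) {
    if (sd(v) == 0) return(c(0, 1))
    ct <- suppressWarnings(cor.test(v, score, method = method, exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  }))
  nConst <- sum(res[, 1L] == 0 & res[, 2L] == 1)
  if (nConst > 0L)
    message(sprintf("%d constant gene(s) assigned cor 0, p 1", nConst))
  data.frame(gene = rownames(exprMatrix), cor = res[, 1L],
             p_value = res[, 2L], p_adjusted = bhAdjust(res[, 2L]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set over-representation test
#'
#' One-sided p of observing at least the given overlap between a selected
#' gene list and a target set, drawn from a finite universe.
#'
#' @param selected genes of interest (must all lie in \code{universe}).
#' @param universe the background gene universe.
#' @param targetSet the gene set being tested; only its intersection with
#'   the universe counts.
#' @return list with \code{statistic} (overlap count), \code{p_value},
#'   \code{group_sizes} (selected, target-in-universe, universe),
#'   \code{direction} (+1 when overlap exceeds its expectation).
#' @export
genesetEnrichment <- function(selected, universe, targetSet) {
  selected <- unique(selected); universe <- unique(universe)
  if (!all(selected %in% universe))
    stop("selected genes must all lie in the universe")
  target <- intersect(unique(targetSet), universe)
  if (!length(target)) stop("target set does not intersect the universe")
  k <- length(intersect(selected, target))
  N <- length(universe); K <- length(target); nSel <- length(selected)
  p <- phyper(k - 1L, K, N - K, nSel, lower.tail = FALSE)
  list(statistic = k, p_value = p,
       group_sizes = c(selected = nSel, target = K, universe = N),
       direction = sign(k - nSel * K / N))
}
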