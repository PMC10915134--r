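# Independent brute-force oracles used to check the package's
# implementations. Each one is a deliberately naive re-derivation from the
# definition, sharing no code with the implementation it checks.

# running-sum enrichment statistic by explicit loop; integer hit/miss
# counters keep the running difference F - B exact, so the maximum and the
# earliest-position tie-break are unambiguous
naiveES <- function(order, sigGenes) {
  m <- sum(order %in% sigGenes)
  n <- length(order)
  hits <- 0
  bestNum <- 0; bestAbs <- -1
  for (i in seq_len(n)) {
    if (order[i] %in% sigGenes) hits <- hits + 1
    misses <- i - hits
    num <- hits * (n - m) - misses * m   # (F - B) * m * (n - m)
    if (abs(num) > bestAbs) { bestAbs <- abs(num); bestNum <- num }
  }
  bestNum / (m * (n - m))
}

# exhaustive permutation z over every signature placement
naiveExhaustiveZ <- function(order, sigGenes) {
  n <- length(order)
  m <- sum(order %in% sigGenes)
  placements <- combn(n, m)
  null <- apply(placements, 2, function(pos) {
    fake <- rep("bg", n); fake[pos] <- "sig"
    naiveES(fake, "sig")
  })
  es <- naiveES(order, sigGenes)
  (es - mean(null)) / sqrt(mean((null - mean(null))^2))
}

# exact two-sided rank-sum p by enumerating every group assignment
naiveWilcoxonP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  picks <- combn(n, nx)
  wAll <- apply(picks, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  ew <- nx * (n - nx) / 2
  mean(abs(wAll - ew) >= abs(wObs - ew) - 1e-12)
}

# two-sided Fisher p by enumerating all tables with the observed margins
naiveFisherP <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(ks, r1, n - r1, c1)
  pObs <- dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# textbook step-up BH: min over j >= i of p(j) * m / j, clipped at 1
naiveBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[o[i]] <- min(1, min(p[o[js]] * m / js))
  }
  adj
}

# Harrell's C by explicit pair enumeration
naiveHarrellC <- function(times, events, risks) {
  conc <- 0; usable <- 0
  n <- length(times)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (times[i] == times[j]) next
    short <- if (times[i] < times[j]) i else j
    long <- if (times[i] < times[j]) j else i
    if (events[short] != 1) next
    usable <- usable + 1
    if (risks[short] > risks[long]) conc <- conc + 1
    else if (risks[short] == risks[long]) conc <- conc + 0.5
  }
  conc / usable
}

# AUC by explicit positive/negative pair comparison
naiveAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# one-covariate Cox partial likelihood (Breslow ties), maximized on a grid
naiveCoxLogPL <- function(beta, times, events, x) {
  ll <- 0
  for (t in unique(times[events == 1])) {
    d <- which(times == t & events == 1)
    atRisk <- which(times >= t)
    ll <- ll + sum(beta * x[d]) -
      length(d) * log(sum(exp(beta * x[atRisk])))
  }
  ll
}

naiveCoxBeta <- function(times, events, x) {
  optimize(function(b) -naiveCoxLogPL(b, times, events, x),
           c(-5, 5), tol = 1e-8)$minimum
}

# exact Cuzick trend statistic p by permutation enumeration, one-sided up
naiveTrendP <- function(values, groups, alternative = "two.sided") {
  l <- as.integer(factor(groups))
  r <- rank(values)
  n <- length(values)
  tObs <- sum(l * r)
  perms <- permn_matrix(n)
  tAll <- apply(perms, 1, function(idx) sum(l * r[idx]))
  et <- mean(tAll)
  switch(alternative,
    greater = mean(tAll >= tObs),
    less = mean(tAll <= tObs),
    two.sided = mean(abs(tAll - et) >= abs(tObs - et) - 1e-12))
}

permn_matrix <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permn_matrix(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

# small labelled random expression matrix
randomExprMatrix <- function(nGenes, nSamples, seed) {
  set.seed(seed)
  matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
         dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                         sprintf("s%03d", seq_len(nSamples))))
}
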