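# Independent oracles: deliberately naive routes, kept separate from the
# package's implementation paths.

# brute-force cross-tabulation: walk the cells one by one
bruteCrossTab <- function(l1, l2) {
  rl <- sort(unique(l1)); cl <- sort(unique(l2))
  cnt <- matrix(0L, length(rl), length(cl),
                dimnames = list(as.character(rl), as.character(cl)))
  for (i in seq_along(l1)) {
    r <- as.character(l1[i]); c <- as.character(l2[i])
    cnt[r, c] <- cnt[r, c] + 1L
  }
  cnt
}

# pair-counting ARI: O(n^2) over cell pairs, no contingency table
pairCountARI <- function(a, b) {
  n <- length(a)
  s11 <- 0; sa <- 0; sb <- 0
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    ta <- a[i] == a[j]; tb <- b[i] == b[j]
    if (ta && tb) s11 <- s11 + 1
    if (ta) sa <- sa + 1
    if (tb) sb <- sb + 1
  }
  np <- n * (n - 1) / 2
  e <- sa * sb / np
  den <- (sa + sb) / 2 - e
  if (den == 0) return(1)
  (s11 - e) / den
}

# NMI from first principles: entropies via tabulation of code combinations
entropyNMI <- function(a, b) {
  n <- length(a)
  ent <- function(v) {
    p <- as.numeric(table(v)) / n
    -sum(p * log(p))
  }
  joint <- as.numeric(table(paste(a, b, sep = "\r"))) / n
  hab <- -sum(joint * log(joint))
  mi <- ent(a) + ent(b) - hab
  if (ent(a) + ent(b) == 0) return(1)
  2 * mi / (ent(a) + ent(b))
}

# Calinski-Harabasz via per-dimension one-way ANOVA decompositions
aovCH <- function(x, g) {
  g <- factor(g)
  ssb <- 0; ssw <- 0
  for (j in seq_len(ncol(x))) {
    an <- anova(lm(x[, j] ~ g))
    ssb <- ssb + an[["Sum Sq"]][1]
    ssw <- ssw + an[["Sum Sq"]][2]
  }
  k <- nlevels(g); n <- nrow(x)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# COPOD re-derived with base::ecdf and e1071::skewness
copodOracle <- function(x) {
  n <- nrow(x); d <- ncol(x)
  ul <- ur <- matrix(0, n, d)
  sk <- numeric(d)
  for (j in seq_len(d)) {
    ul[, j] <- -log(ecdf(x[, j])(x[, j]))
    ur[, j] <- -log(ecdf(-x[, j])(-x[, j]))
    sk[j] <- sign(e1071::skewness(x[, j], type = 1))
    if (is.na(sk[j])) sk[j] <- 0
  }
  us <- matrix(0, n, d)
  for (j in seq_len(d))
    us[, j] <- ul[, j] * -sign(sk[j] - 1) + ur[, j] * sign(sk[j] + 1)
  rowSums(pmax(us, (ul + ur) / 2))
}

randomLabeling <- function(n, kMax = 8L) {
  k <- sample.int(kMax - 1L, 1L) + 1L
  pmin(sample.int(k, n, replace = TRUE), k)
}

# labelings realizing the 2x2 worked table counts [[8,0],[2,10]]
handTraceFixture <- function() {
  c1 <- ClusterLabels(labels = rep(c(1L, 2L, 2L), c(8, 2, 10)))
  c2 <- ClusterLabels(labels = rep(c(1L, 1L, 2L), c(8, 2, 10)))
  ct <- buildCrossTab(c1, c2)
  list(c1 = c1, c2 = c2, ct = ct,
       mm = matchLabels(ct, c1, c2, axis = "columns"),
       cv = cvStats(ct, "columns"))
}
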