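# Independent oracles used across the test files. These deliberately take
# naive computational routes (explicit inverses, pairwise MRCA search)
# so they share no code path with the implementation they check.

# VCV by explicit pairwise MRCA search on root-to-node paths
bruteVCV <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  parent <- integer(n + tree$Nnode)
  blen <- numeric(n + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) {
    parent[tree$edge[k, 2]] <- tree$edge[k, 1]
    blen[tree$edge[k, 2]] <- tree$edge.length[k]
  }
  pathOf <- function(i) {           # node list from tip up to root
    p <- i
    while (i != root) { i <- parent[i]; p <- c(p, i) }
    p
  }
  depthOf <- function(i) {
    d <- 0
    while (i != root) { d <- d + blen[i]; i <- parent[i] }
    d
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    mrca <- intersect(pathOf(i), pathOf(j))[1]
    C[i, j] <- depthOf(mrca)
  }
  C
}

# GLS coefficients / SEs by explicit matrix inversion (never Cholesky)
bruteGLS <- function(y, X, V) {
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  e <- y - X %*% beta
  n <- length(y); p <- ncol(X)
  s2 <- as.numeric(t(e) %*% Vi %*% e) / (n - p)
  se <- sqrt(diag(solve(XtVi %*% X)) * s2)
  list(beta = as.vector(beta), se = se, sigma2_resid = s2,
       resid = as.vector(e))
}

# a random ultrametric tree with positive terminal branches
randomUltraTree <- function(n, seed) {
  cfg <- syntheticConfig(n_tips = n, seed = seed)
  simulateTree(cfg)
}

studyTable <- function(...) loadTraitTable(...)
studyTree <- function() readChronogram()
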