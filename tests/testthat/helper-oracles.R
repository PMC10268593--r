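# Independent oracles used to check the implementation. These deliberately
# use the slowest, most literal formulation of each quantity and share no
# code with the package.

# N50/L50 by literal definition: sort descending, scan the cumulative sum.
oracle_n50 <- function(lengths) {
  sl <- sort(lengths, decreasing = TRUE)
  total <- sum(sl)
  run <- 0
  for (i in seq_along(sl)) {
    run <- run + sl[i]
    if (run >= total / 2) return(list(n50 = sl[i], l50 = i))
  }
}

# Two-sided exact binomial p by exhaustive enumeration: sum the
# probabilities of all outcomes no more likely than the observed one.
# Mathematically tied probabilities (e.g. P(k) = P(n-k) at w = 1/2) come
# out of dbinom with different last-bit rounding, so ties are recognized
# with a 1e-9 relative tolerance; at n <= 12 genuinely distinct outcome
# probabilities differ by far more than that.
oracle_binom_p <- function(obs, n, w) {
  d <- dbinom(0:n, n, w)
  sum(d[d <= d[obs + 1] * (1 + 1e-9)])
}

# --- exhaustive topology search ---------------------------------------
# A topology on n taxa is a set of n-3 pairwise-compatible non-trivial
# splits. For each candidate topology, branch lengths are fit by ordinary
# least squares on the path-indicator system; the additive matrix's true
# topology is the unique one with zero residual.

oracle_all_splits <- function(taxa) {
  n <- length(taxa)
  rest <- setdiff(taxa, taxa[1])
  out <- list()
  for (k in 2:(n - 2)) {
    cm <- utils::combn(rest, k, simplify = FALSE)
    out <- c(out, lapply(cm, sort))
  }
  out
}

oracle_compatible <- function(a, b, taxa) {
  ac <- setdiff(taxa, a)
  bc <- setdiff(taxa, b)
  length(intersect(a, b)) == 0 || length(intersect(a, bc)) == 0 ||
    length(intersect(ac, b)) == 0 || length(intersect(ac, bc)) == 0
}

oracle_topologies <- function(taxa) {
  splits <- oracle_all_splits(taxa)
  k <- length(taxa) - 3L
  if (k == 0L) return(list(list()))
  idx <- utils::combn(length(splits), k, simplify = FALSE)
  keep <- Filter(function(ii) {
    if (length(ii) == 1L) return(TRUE)
    prs <- utils::combn(ii, 2, simplify = FALSE)
    all(vapply(prs, function(p) {
      oracle_compatible(splits[[p[1]]], splits[[p[2]]], taxa)
    }, logical(1)))
  }, idx)
  lapply(keep, function(ii) splits[ii])
}

oracle_rss <- function(D, taxa, splits) {
  prs <- utils::combn(taxa, 2, simplify = FALSE)
  ncol <- length(taxa) + length(splits)
  A <- matrix(0, length(prs), ncol)
  y <- numeric(length(prs))
  for (r in seq_along(prs)) {
    i <- prs[[r]][1]; j <- prs[[r]][2]
    A[r, match(i, taxa)] <- 1
    A[r, match(j, taxa)] <- 1
    if (length(splits) > 0L) {
      for (s in seq_along(splits)) {
        if (xor(i %in% splits[[s]], j %in% splits[[s]])) {
          A[r, length(taxa) + s] <- 1
        }
      }
    }
    y[r] <- D[i, j]
  }
  fit <- qr.solve(A, y)
  sum((A %*% fit - y)^2)
}

# Best topology (as a canonical split set) by exhaustive least squares.
oracle_best_topology <- function(D) {
  taxa <- sort(rownames(D))
  tops <- oracle_topologies(taxa)
  rss <- vapply(tops, function(sp) oracle_rss(D, taxa, sp), numeric(1))
  canonical_splitset(tops[[which.min(rss)]], taxa)
}

canonical_splitset <- function(splits, taxa) {
  t1 <- sort(taxa)[1]
  canon <- lapply(splits, function(s) {
    if (t1 %in% s) sort(setdiff(taxa, s)) else sort(s)
  })
  canon[order(vapply(canon, paste, character(1), collapse = "|"))]
}

# Splits of a phylo tree, computed through ape only (not through the
# package's own bipartition code).
oracle_tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(labs)
  sets <- lapply(pp, function(i) sort(labs[i]))
  sets <- Filter(function(s) length(s) >= 2 && length(s) <= n - 2, sets)
  unique(canonical_splitset(sets, labs))
}

same_topology <- function(tree, splitset) {
  got <- oracle_tree_splits(tree)
  if (length(got) != length(splitset)) return(FALSE)
  all(vapply(seq_along(got), function(i) {
    identical(got[[i]], splitset[[i]])
  }, logical(1)))
}

# random additive tree and its exact distance matrix
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}
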