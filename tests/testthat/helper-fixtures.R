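# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive (explicit set arithmetic, path
# enumeration, full permutation scans) and never call the code paths they
# check.

## the worked three-taxon tree used throughout: ((A:1,B:1):1,C:2);
tiny_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

## small valid abundance matrix
tiny_counts <- function() {
  m <- matrix(c(5L, 1L, 0L, 0L, 2L, 7L), nrow = 3,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  m
}

## random abundance table over nt taxa and ns samples
random_counts <- function(nt, ns, seed, depth = 200) {
  set.seed(seed)
  m <- sapply(seq_len(ns), function(i) {
    p <- rexp(nt)
    as.integer(rmultinom(1, depth, p / sum(p)))
  })
  dimnames(m) <- list(sprintf("t%03d", seq_len(nt)), sprintf("s%03d", seq_len(ns)))
  m
}

## --- oracles -------------------------------------------------------------

## pairwise tip distances by Floyd-Warshall over the tree's edge graph
oracle_patristic <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  d <- matrix(Inf, nn, nn); diag(d) <- 0
  for (k in seq_len(nrow(tree$edge))) {
    i <- tree$edge[k, 1]; j <- tree$edge[k, 2]
    d[i, j] <- d[j, i] <- tree$edge.length[k]
  }
  for (k in seq_len(nn)) for (i in seq_len(nn)) for (j in seq_len(nn)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  tips <- seq_along(tree$tip.label)
  out <- d[tips, tips]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

## Sorensen partition by explicit set arithmetic on taxon name sets
oracle_sorensen <- function(taxa_x, taxa_y) {
  a <- length(intersect(taxa_x, taxa_y))
  b <- length(setdiff(taxa_x, taxa_y))
  c <- length(setdiff(taxa_y, taxa_x))
  bsor <- (b + c) / (2 * a + b + c)
  bsim <- if (b + c == 0) 0 else min(b, c) / (a + min(b, c))
  list(beta_sor = bsor, beta_sim = bsim, beta_sne = bsor - bsim)
}

## betaMNTD by explicit nearest-taxon enumeration over a distance matrix
oracle_bmntd <- function(D, x, y, weighted = TRUE) {
  px <- names(x)[x > 0]; py <- names(y)[y > 0]
  wx <- if (weighted) x[px] / sum(x[px]) else rep(1 / length(px), length(px))
  wy <- if (weighted) y[py] / sum(y[py]) else rep(1 / length(py), length(py))
  mx <- vapply(px, function(i) min(vapply(py, function(j) D[i, j], 1)), 1)
  my <- vapply(py, function(j) min(vapply(px, function(i) D[i, j], 1)), 1)
  0.5 * (sum(wx * mx) + sum(wy * my))
}

## one-factor PERMANOVA pseudo-F from first principles (Gower identity:
## within/total sums of squared distances)
oracle_pseudo_F <- function(dm, groups) {
  n <- nrow(dm); G <- dm^2
  ss_tot <- sum(G[upper.tri(G)]) / n
  ss_w <- 0
  for (lv in unique(groups)) {
    ix <- which(groups == lv)
    sub <- G[ix, ix, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(ix)
  }
  a <- length(unique(groups))
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

## all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
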