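# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (enumeration, direct formulas) and never call
# the implementation paths they are checking.

# Mk model: likelihood and marginals by summation over every internal-state
# assignment (feasible for <= ~8 internal nodes).
enum_mk <- function(tree, states, rate) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  internal <- (n + 1L):nn
  P <- function(t) {
    s <- (1 + exp(-2 * rate * t)) / 2
    matrix(c(s, 1 - s, 1 - s, s), 2L, 2L)
  }
  tot <- 0
  marg <- matrix(0, nn, 2L)
  for (mask in 0:(2^length(internal) - 1L)) {
    st <- integer(nn)
    st[1:n] <- states[tree$tip.label]
    st[internal] <- bitwAnd(mask %/% 2^(seq_along(internal) - 1L), 1L)
    pr <- 0.5
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P(tree$edge.length[e])[st[tree$edge[e, 1L]] + 1L,
                                        st[tree$edge[e, 2L]] + 1L]
    tot <- tot + pr
    for (v in seq_len(nn)) marg[v, st[v] + 1L] <- marg[v, st[v] + 1L] + pr
  }
  list(loglik = log(tot), marg = marg / tot)
}

# Fitch parsimony by enumeration: minimum change count and per-node sets of
# states attainable in at least one minimum-change labelling.
enum_mp <- function(tree, states) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  internal <- (n + 1L):nn
  best <- Inf
  sets <- vector("list", nn)
  for (mask in 0:(2^length(internal) - 1L)) {
    st <- integer(nn)
    st[1:n] <- states[tree$tip.label]
    st[internal] <- bitwAnd(mask %/% 2^(seq_along(internal) - 1L), 1L)
    ch <- sum(st[tree$edge[, 1L]] != st[tree$edge[, 2L]])
    if (ch < best) {
      best <- ch
      sets <- lapply(seq_len(nn), function(v) st[v])
    } else if (ch == best) {
      for (v in seq_len(nn)) sets[[v]] <- union(sets[[v]], st[v])
    }
  }
  list(min_changes = best, state_sets = lapply(sets, sort))
}

# Benjamini-Hochberg by its O(n^2) textbook definition:
# padj_i = min over {j : p_j >= p_i} of m * p_j / rank(p_j), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(vapply(js, function(j) m * p[j] / sum(p <= p[j]), numeric(1))))
  }, numeric(1))
}

# random binary tree with occasional multifurcations and informative states
rand_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips)
  if (stats::runif(1) < 0.3) tr <- ape::di2multi(tr, tol = 0.25)
  tr
}

# small-scale simulation scenario used by fast end-to-end tests
small_scenario <- function(n_background = 2000) {
  default_scenario(n_background = n_background)
}

# convenience: run the normalization front-end of the DE stage
de_prep <- function(sim) {
  filt <- filter_low_counts(sim$counts)
  sf <- size_factors_median_ratio(filt)
  disp <- estimate_dispersion(filt, sf, sim$design)
  list(counts = filt, sf = sf, disp = disp,
       rld = regularized_log(filt, sf))
}

options(detoxshift.verbose = FALSE)
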