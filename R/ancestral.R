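#' @name ancestral
#' @title Ancestral host-state reconstruction under the two-state Mk model
#'
#' @description
#' Binary host presence/absence characters evolve along the phylogeny under
#' the symmetric (equal-rates) Mk model with transition rate q. Over a branch
#' of length t the probability of staying in a state is (1 + exp(-2qt))/2 and
#' of changing is (1 - exp(-2qt))/2. The root prior is the stationary
#' distribution (1/2, 1/2). These routines implement the pruning likelihood,
#' maximum-likelihood rate estimation, marginal (all-tips-conditioned) node
#' probabilities, and most-parsimonious-reconstruction state sets, natively
#' supporting multifurcating nodes.
NULL

# internal: topology bookkeeping shared by all tree walkers
tree_info <- function(tree) {
  if (!inherits(tree, "phylo")) ds_stop("ancestral", "tree must be a phylo object")
  if (is.null(tree$edge.length)) ds_stop("ancestral", "tree has no branch lengths")
  if (any(tree$edge.length < 0)) ds_stop("ancestral", "negative branch length")
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  children <- vector("list", n + nnode)
  edge_len <- numeric(n + nnode)   # branch length above each node
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    children[[p]] <- c(children[[p]], c)
    edge_len[c] <- tree$edge.length[e]
  }
  root <- n + 1L
  # postorder: children before parents, root last
  post <- c(ape::reorder.phylo(tree, "postorder")$edge[, 2L], root)
  list(n = n, nnode = nnode, root = root, children = children,
       edge_len = edge_len, postorder = post)
}

# internal: align a states vector to tip order; states coerced to 0/1
align_tip_states <- function(tree, tip_states) {
  n <- length(tree$tip.label)
  if (!is.null(names(tip_states))) {
    miss <- setdiff(tree$tip.label, names(tip_states))
    if (length(miss))
      ds_stop("ancestral", "tips missing a state: ", paste(miss, collapse = ", "))
    tip_states <- tip_states[tree$tip.label]
  } else if (length(tip_states) != n) {
    ds_stop("ancestral", "tip_states length does not match number of tips")
  }
  s <- as.integer(tip_states)
  if (any(is.na(s)) || !all(s %in% c(0L, 1L)))
    ds_stop("ancestral", "tip states must be 0/1")
  s
}

# internal: 2x2 symmetric Mk transition matrix over branch length t at rate q
mk_pmatrix <- function(q, t) {
  stay <- (1 + exp(-2 * q * t)) / 2
  matrix(c(stay, 1 - stay, 1 - stay, stay), 2L, 2L)
}

# internal: scaled post-order partial likelihoods
# returns list(up = (n+nnode) x 2 matrix, logscale = total log scaling)
mk_partials <- function(info, tip01, rate) {
  nn <- info$n + info$nnode
  up <- matrix(1, nn, 2L)
  for (i in seq_len(info$n)) up[i, ] <- c(tip01[i] == 0L, tip01[i] == 1L)
  logscale <- 0
  for (v in info$postorder) {
    kids <- info$children[[v]]
    if (is.null(kids)) next
    row <- c(1, 1)
    for (k in kids) {
      P <- mk_pmatrix(rate, info$edge_len[k])
      row <- row * as.vector(P %*% up[k, ])
    }
    s <- sum(row)
    if (s <= 0) return(list(up = up, logscale = -Inf, zero = TRUE))
    up[v, ] <- row / s
    logscale <- logscale + log(s)
  }
  list(up = up, logscale = logscale, zero = FALSE)
}

#' Log-likelihood of binary tip states under the equal-rates Mk model
#'
#' Computed by Felsenstein pruning (post-order partial likelihoods) with a
#' stationary (1/2, 1/2) root prior. Zero-length branches use exact identity
#' transitions.
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @param tip_states 0/1 vector, named by tip label or in tip order.
#' @param rate non-negative transition rate per unit branch length.
#' @return the log-likelihood (a finite scalar).
#' @export
mk_likelihood <- function(tree, tip_states, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
    ds_stop("ancestral", "rate must be a non-negative scalar")
  info <- tree_info(tree)
  s <- align_tip_states(tree, tip_states)
  part <- mk_partials(info, s, rate)
  if (part$zero) return(-Inf)  # conflicting tips at rate 0
  log(sum(0.5 * part$up[info$root, ])) + part$logscale
}

#' Maximum-likelihood estimate of the Mk transition rate
#'
#' One-dimensional bounded optimization of the pooled log-likelihood over
#' rate in [1e-9, 100]. When every tip shares one state the likelihood is
#' maximized at the zero-rate boundary and 0 is returned.
#'
#' @param tree rooted `phylo` tree.
#' @param tip_states 0/1 vector for one character, or a matrix with one
#'   column per character (rows = tips, named or tip-ordered); characters
#'   share one pooled rate.
#' @param lower,upper optimization bounds.
#' @param tol convergence tolerance passed to [stats::optimize()].
#' @return the fitted rate (scalar).
#' @export
estimate_rate_ml <- function(tree, tip_states, lower = 1e-9, upper = 100,
                             tol = 1e-8) {
  info <- tree_info(tree)
  S <- if (is.matrix(tip_states)) tip_states else matrix(tip_states, ncol = 1L,
         dimnames = list(names(tip_states), NULL))
  cols <- lapply(seq_len(ncol(S)), function(j) {
    v <- S[, j]
    if (!is.null(rownames(S))) names(v) <- rownames(S)
    align_tip_states(tree, v)
  })
  if (all(vapply(cols, function(s) length(unique(s)) == 1L, logical(1))))
    return(0)
  negll <- function(q) {
    -sum(vapply(cols, function(s) {
      p <- mk_partials(info, s, q)
      if (p$zero) return(-Inf)
      log(sum(0.5 * p$up[info$root, ])) + p$logscale
    }, numeric(1)))
  }
  opt <- stats::optimize(negll, interval = c(lower, upper), tol = tol)
  opt$minimum
}

#' Marginal ancestral state probabilities
#'
#' For every node, the probability of each state conditional on ALL tip
#' states, obtained by combining upward (pruning) partials with a downward
#' pass. Tips receive degenerate vectors.
#'
#' @param tree rooted `phylo` tree.
#' @param tip_states 0/1 vector, named by tip label or in tip order.
#' @param rate Mk transition rate (e.g. from [estimate_rate_ml()]).
#' @return matrix (tips + internal nodes) x 2, columns `absent`/`present`;
#'   rows sum to 1; row order is the phylo node numbering.
#' @export
marginal_ancestral <- function(tree, tip_states, rate) {
  if (!is.numeric(rate) || rate < 0) ds_stop("ancestral", "rate must be >= 0")
  info <- tree_info(tree)
  s <- align_tip_states(tree, tip_states)
  part <- mk_partials(info, s, rate)
  if (part$zero)
    ds_stop("ancestral", "tip states have zero likelihood at this rate")
  up <- part$up
  nn <- info$n + info$nnode
  out <- matrix(NA_real_, nn, 2L)
  out[info$root, ] <- c(0.5, 0.5)
  # preorder: parents before children (reverse postorder)
  pre <- rev(info$postorder)
  for (v in pre) {
    kids <- info$children[[v]]
    if (is.null(kids)) next
    # messages from each child's siblings, as seen from v
    msg <- lapply(kids, function(k)
      as.vector(mk_pmatrix(rate, info$edge_len[k]) %*% up[k, ]))
    names(msg) <- as.character(kids)
    for (i in seq_along(kids)) {
      k <- kids[i]
      sib <- c(1, 1)
      for (j in seq_along(kids)) if (j != i) sib <- sib * msg[[j]]
      P <- mk_pmatrix(rate, info$edge_len[k])
      out[k, ] <- as.vector(t(P) %*% (out[v, ] * sib))
    }
  }
  marg <- up * out
  marg <- marg / rowSums(marg)
  colnames(marg) <- c("absent", "present")
  marg
}

#' Most-parsimonious-reconstruction state sets (Fitch/Sankoff)
#'
#' Unit-cost Sankoff dynamic programming up and down the tree gives, for every
#' node, the set of states attainable in at least one labelling achieving the
#' minimum number of changes, together with that minimum.
#'
#' @param tree rooted `phylo` tree (branch lengths ignored).
#' @param tip_states 0/1 vector, named by tip label or in tip order.
#' @return list with `min_changes` (integer) and `state_sets` (list over
#'   nodes in phylo numbering; each a subset of c(0, 1)).
#' @export
mp_reconstruct <- function(tree, tip_states) {
  info <- tree_info(tree)
  s <- align_tip_states(tree, tip_states)
  nn <- info$n + info$nnode
  INF <- nn + 10
  up <- matrix(INF, nn, 2L)
  for (i in seq_len(info$n)) up[i, s[i] + 1L] <- 0
  for (v in info$postorder) {
    kids <- info$children[[v]]
    if (is.null(kids)) next
    cost <- c(0, 0)
    for (k in kids)
      cost <- cost + vapply(1:2, function(sv)
        min(up[k, ] + (1:2 != sv)), numeric(1))
    up[v, ] <- cost
  }
  minc <- min(up[info$root, ])
  down <- matrix(INF, nn, 2L)
  down[info$root, ] <- 0
  for (v in rev(info$postorder)) {
    kids <- info$children[[v]]
    if (is.null(kids)) next
    # contribution of each child to the parent's up cost, per parent state
    contrib <- lapply(kids, function(k)
      vapply(1:2, function(sv) min(up[k, ] + (1:2 != sv)), numeric(1)))
    for (i in seq_along(kids)) {
      k <- kids[i]
      rest <- down[v, ]
      for (j in seq_along(kids)) if (j != i) rest <- rest + contrib[[j]]
      down[k, ] <- vapply(1:2, function(sk)
        min(rest + (1:2 != sk)), numeric(1))
    }
  }
  total <- up + down
  sets <- lapply(seq_len(nn), function(v) which(total[v, ] == minc) - 1L)
  if (any(lengths(sets) == 0L)) ds_stop("ancestral", "empty MP state set")
  list(min_changes = as.integer(minc), state_sets = sets)
}

#' Per-character ancestral host report
#'
#' For every host taxon (column of the host-range matrix) fits the Mk rate by
#' maximum likelihood, computes the marginal root probability of presence,
#' and the maximum-parsimony root state set.
#'
#' @param tree rooted `phylo` tree; every tip must appear as a row of `mat`.
#' @param mat binary host-range matrix (rows = species groups / tips).
#' @return data.frame with columns `character`, `rate`, `root_p_present`,
#'   `mp_root_set`, `mp_changes`, sorted by `root_p_present` descending.
#' @export
ancestral_host_report <- function(tree, mat) {
  miss <- setdiff(tree$tip.label, rownames(mat))
  if (length(miss))
    ds_stop("ancestral", "tips absent from host matrix: ",
            paste(miss, collapse = ", "))
  root <- length(tree$tip.label) + 1L
  rows <- lapply(colnames(mat), function(ch) {
    states <- setNames(mat[tree$tip.label, ch], tree$tip.label)
    rate <- estimate_rate_ml(tree, states)
    marg <- marginal_ancestral(tree, states, rate)
    mp <- mp_reconstruct(tree, states)
    data.frame(character = ch, rate = rate,
               root_p_present = marg[root, "present"],
               mp_root_set = paste(mp$state_sets[[root]], collapse = "/"),
               mp_changes = mp$min_changes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$root_p_present), , drop = FALSE]
}
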