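#' Arcsine square-root transform of proportions
#'
#' The classical variance-stabilizing transform for proportion data:
#' asin(sqrt(p)), mapping [0, 1] onto [0, pi/2] radians.
#'
#' @param p proportions in the closed unit interval.
#' @return transformed values in radians.
#' @export
arcsine_sqrt <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    ds_stop("performance", "proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Two-way ANOVA of survival proportions
#'
#' Arcsine-square-root transforms the proportions and fits
#' `aov(value ~ species * plant)` (Type-I sums of squares on the balanced
#' assay design), returning the standard species / plant / interaction /
#' residual decomposition.
#'
#' @param survival a [survival_table()].
#' @param transform apply [arcsine_sqrt()] first (default TRUE).
#' @return data.frame with rows species, plant, interaction, residual and
#'   columns `df`, `ss`, `f`, `p`.
#' @export
two_way_anova <- function(survival, transform = TRUE) {
  stopifnot(inherits(survival, "survival_table"))
  tab <- table(survival$species, survival$plant)
  if (any(tab == 0)) ds_stop("performance", "empty species x plant cell")
  y <- if (transform) arcsine_sqrt(survival$proportion_survived)
       else survival$proportion_survived
  dat <- data.frame(y = y, species = factor(survival$species),
                    plant = factor(survival$plant))
  can_interact <- any(tab >= 2)
  form <- if (can_interact) y ~ species * plant else y ~ species + plant
  fit <- aov(form, data = dat)
  sm <- summary(fit)[[1L]]
  rn <- trimws(rownames(sm))
  pick <- function(label) {
    i <- match(label, rn)
    if (is.na(i)) c(df = NA_real_, ss = NA_real_, f = NA_real_, p = NA_real_)
    else c(df = sm[i, "Df"], ss = sm[i, "Sum Sq"],
           f = if ("F value" %in% colnames(sm)) sm[i, "F value"] else NA_real_,
           p = if ("Pr(>F)" %in% colnames(sm)) sm[i, "Pr(>F)"] else NA_real_)
  }
  out <- rbind(species = pick("species"), plant = pick("plant"),
               interaction = pick("species:plant"),
               residual = pick("Residuals"))
  out <- as.data.frame(out)
  out$p[rownames(out) == "residual"] <- NA_real_
  out$f[rownames(out) == "residual"] <- NA_real_
  # all-equal responses: zero SS everywhere -> F = 0, p = 1 by convention
  zero <- !is.na(out$ss) & out$ss == 0 & rownames(out) != "residual"
  if (all(dat$y == dat$y[1L])) {
    out$f[rownames(out) != "residual"] <- 0
    out$p[rownames(out) != "residual"] <- 1
  } else if (any(zero)) {
    out$f[zero] <- 0; out$p[zero] <- 1
  }
  out
}

#' Dunn-Sidak sequential-Bonferroni pairwise comparisons
#'
#' Welch t-tests between all group pairs, ordered by ascending p-value. At
#' step i (with m pairs in total) the observed p is compared to the
#' Dunn-Sidak level 1 - (1 - alpha)^(1/(m - i + 1)); testing stops at the
#' first non-rejection (step-down sequential Bonferroni with the Sidak
#' correction). Groups are then assigned compact letters such that two
#' groups share a letter iff they were not significantly different.
#'
#' @param values numeric observations.
#' @param groups group labels, same length as `values`.
#' @param alpha familywise level (default 0.05).
#' @return list: `pairs` (data.frame pair/p/alpha_step/significant),
#'   `letters` (named character per group), `alpha`.
#' @export
dunn_sidak_pairwise <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  if (length(levs) < 2L) ds_stop("performance", "need >= 2 groups")
  obs <- split(as.numeric(values), groups)
  small <- names(obs)[lengths(obs) < 2L]
  if (length(small))
    ds_stop("performance", "groups with < 2 observations: ",
            paste(small, collapse = ", "))
  prs <- t(combn(levs, 2L))
  pvals <- apply(prs, 1L, function(pr) {
    a <- obs[[pr[1L]]]; b <- obs[[pr[2L]]]
    if (var(a) == 0 && var(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b)$p.value
  })
  seq_ <- sequential_sidak(pvals, alpha)
  pairs <- data.frame(group_a = prs[, 1L], group_b = prs[, 2L], p = pvals,
                      alpha_step = seq_$alpha_step,
                      significant = seq_$significant,
                      stringsAsFactors = FALSE)
  sig <- seq_$significant
  list(pairs = pairs,
       letters = compact_letters(levs, prs, sig,
                                 rank_means = vapply(obs[levs], mean, numeric(1))),
       alpha = alpha)
}

#' Step-down sequential Sidak testing of a p-value family
#'
#' Orders the m p-values ascending; at step i the smallest remaining p is
#' compared to 1 - (1 - alpha)^(1/(m - i + 1)) and testing stops at the
#' first non-rejection. The first-step level equals the single-step Sidak
#' level, so the procedure rejects a superset of single-step Sidak (and of
#' Bonferroni) rejections.
#'
#' @param p vector of p-values.
#' @param alpha familywise level.
#' @return list with `significant` (logical, input order) and `alpha_step`
#'   (the per-p step level each was compared against).
#' @export
sequential_sidak <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  alpha_step <- numeric(m); sig <- logical(m)
  rejecting <- TRUE
  for (i in seq_len(m)) {
    alpha_step[i] <- 1 - (1 - alpha)^(1 / (m - i + 1))
    if (rejecting && p[ord[i]] <= alpha_step[i]) sig[ord[i]] <- TRUE
    else rejecting <- FALSE
  }
  list(significant = sig, alpha_step = alpha_step[order(ord)])
}

# internal: compact letter display from the non-significance graph.
# Maximal cliques (brute force; group counts here are tiny), ordered by the
# mean value of their best-ranked member, become letters a, b, c, ...
compact_letters <- function(levs, pairs, sig, rank_means) {
  k <- length(levs)
  adj <- matrix(TRUE, k, k, dimnames = list(levs, levs))
  for (i in seq_len(nrow(pairs)))
    if (sig[i]) {
      adj[pairs[i, 1L], pairs[i, 2L]] <- FALSE
      adj[pairs[i, 2L], pairs[i, 1L]] <- FALSE
    }
  subsets <- lapply(seq_len(2^k - 1L), function(mask)
    levs[bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0])
  is_clique <- vapply(subsets, function(s)
    all(adj[s, s, drop = FALSE]), logical(1))
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(seq_along(cliques), function(i)
    !any(vapply(seq_along(cliques), function(j)
      j != i && all(cliques[[i]] %in% cliques[[j]]), logical(1))),
    logical(1))]
  ord <- order(vapply(maximal, function(s) min(rank(-rank_means)[s]), numeric(1)))
  maximal <- maximal[ord]
  lab <- setNames(rep("", k), levs)
  for (i in seq_along(maximal))
    lab[maximal[[i]]] <- paste0(lab[maximal[[i]]], letters[i])
  lab
}

#' Within-plant pairwise species comparisons with letter groupings
#'
#' For each plant, runs [dunn_sidak_pairwise()] on the transformed survival
#' proportions of the six species (the per-panel analysis of the survival
#' figure). A full-design mode pooling all cells is available via
#' `by_plant = FALSE`.
#'
#' @param survival a [survival_table()].
#' @param alpha familywise level.
#' @param by_plant compare species within each plant (default) or across all
#'   species x plant cells.
#' @return named list per plant (or a single element "all") of
#'   [dunn_sidak_pairwise()] results.
#' @export
performance_letters <- function(survival, alpha = 0.05, by_plant = TRUE) {
  y <- arcsine_sqrt(survival$proportion_survived)
  if (by_plant) {
    plants <- unique(survival$plant)
    out <- lapply(plants, function(p) {
      idx <- survival$plant == p
      dunn_sidak_pairwise(y[idx], survival$species[idx], alpha)
    })
    names(out) <- plants
    out
  } else {
    list(all = dunn_sidak_pairwise(
      y, paste(survival$species, survival$plant, sep = "|"), alpha))
  }
}
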