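#' Default simulation scenario
#'
#' Parameters of the synthetic data generator, chosen to emulate the scale
#' and structure the analysis assumes: six species in two host-performance
#' groups, four plants, three replicates, a 298-gene detox catalog with the
#' canonical family composition embedded in a large background, and
#' negative-binomial counts whose log2-scale mean model carries species,
#' plant and group-structured plant-response effects.
#'
#' Background genes carry species effects and plant effects shared by all
#' species (no group structure), so host-plant association dominates their
#' profiles. Detox genes carry species effects, a per-gene constitutive
#' group signature (polarized between the high- and low-performance groups,
#' mirroring the tendency of low performers to lower detox expression), and
#' planted class effects: constitutively unique genes (per-species shifts),
#' single-species plastic responders, and shared "machinery" genes whose
#' plant responses are common to one performance group (induced in the high
#' group or suppressed in the low group).
#'
#' @param n_background number of non-catalog genes.
#' @param detox_families named family counts of the catalog.
#' @param grouping a [performance_grouping()] over the design species.
#' @return a `scenario` parameter list consumed by [simulate_counts()].
#' @export
default_scenario <- function(n_background = 25000,
                             detox_families = c(P450 = 104, GST = 25,
                                                COE = 24, UDPGT = 71,
                                                SULT = 20, ABC = 54),
                             grouping = default_grouping()) {
  list(
    n_background = n_background,
    detox_families = detox_families,
    grouping = grouping,
    base_log2_background = c(mean = 5, sd = 2),
    base_log2_detox = c(mean = 7, sd = 1.2),
    dispersion_meanlog = log(0.015), dispersion_sdlog = 0.5,
    lib_factor_range = c(0.5, 1.5),
    sd_species_background = 0.5,
    sd_plant_background = 1.0,
    sd_species_detox = 0.3,
    sd_plant_detox = 0,
    sd_group_detox = 0.4,
    n_constitutive_over = 6, n_constitutive_under = 4,  # per species
    constitutive_effect = 3,
    n_plastic_single = 40, plastic_effect = 2,
    n_machinery_induced = 50, n_machinery_suppressed = 30,
    machinery_effect = 2)
}

# internal: draw counts row-block from the NB mean model
nb_draw <- function(mu, alpha) {
  out <- numeric(length(mu))
  tiny <- alpha < 1e-12
  if (any(tiny)) out[tiny] <- stats::rpois(sum(tiny), mu[tiny])
  if (any(!tiny)) out[!tiny] <- rnbinom(sum(!tiny), mu = mu[!tiny],
                                        size = 1 / alpha[!tiny])
  out
}

#' Simulate a count matrix with known ground truth
#'
#' Counts are drawn NB(mean = lib_factor x 2^eta, dispersion alpha) where
#' eta = base + species effect + plant effect + interaction effect (all on
#' the log2 scale) and Var = mu + alpha mu^2. The returned truth object
#' records every effect and the planted class labels.
#'
#' @param design a [sample_design()].
#' @param scenario parameter list from [default_scenario()] (or a modified
#'   copy).
#' @param seed integer seed; all draws are derived from it.
#' @return list with `counts` (integer gene x sample matrix), `catalog`
#'   (a [gene_catalog()]), `truth` (list: `genes` data.frame, effect arrays,
#'   `lib_factors`), and `design`.
#' @export
simulate_counts <- function(design, scenario = default_scenario(), seed = 1) {
  stopifnot(inherits(design, "sample_design"))
  sc <- scenario
  if (any(unlist(sc$lib_factor_range) <= 0))
    ds_stop("simulate", "library factors must be positive")
  species <- sort(unique(design$species))
  plants <- HOST_PLANTS
  noncommon <- setdiff(plants, "eggplant")
  set.seed(sub_seed(seed, "counts"))

  n_detox <- sum(sc$detox_families)
  n_genes <- sc$n_background + n_detox
  detox_ids <- sprintf("detox%04d", seq_len(n_detox))
  bg_ids <- sprintf("bg%05d", seq_len(sc$n_background))
  gene_id <- c(detox_ids, bg_ids)
  is_detox <- c(rep(TRUE, n_detox), rep(FALSE, sc$n_background))
  family <- c(rep(names(sc$detox_families), sc$detox_families),
              rep(NA_character_, sc$n_background))
  catalog <- gene_catalog(detox_ids, family[seq_len(n_detox)])

  base <- numeric(n_genes)
  base[is_detox] <- rnorm(n_detox, sc$base_log2_detox["mean"],
                          sc$base_log2_detox["sd"])
  base[!is_detox] <- rnorm(sc$n_background, sc$base_log2_background["mean"],
                           sc$base_log2_background["sd"])
  alpha <- stats::rlnorm(n_genes, sc$dispersion_meanlog, sc$dispersion_sdlog)
  if (any(alpha <= 0)) ds_stop("simulate", "non-positive dispersion")

  sp_eff <- matrix(rnorm(n_genes * length(species), 0,
                         ifelse(is_detox, sc$sd_species_detox,
                                sc$sd_species_background)),
                   n_genes, length(species),
                   dimnames = list(gene_id, species))
  pl_eff <- matrix(rnorm(n_genes * length(plants), 0,
                         ifelse(is_detox, sc$sd_plant_detox,
                                sc$sd_plant_background)),
                   n_genes, length(plants),
                   dimnames = list(gene_id, plants))
  inter <- array(0, dim = c(n_genes, length(species), length(plants)),
                 dimnames = list(gene_id, species, plants))
  # performance-group signature of the detox system: every catalog gene gets
  # a group-polarized constitutive shift (absent from background genes)
  grp_eff <- rnorm(n_genes, 0, sc$sd_group_detox) * is_detox
  grp_sign <- ifelse(species %in% sc$grouping$high, 0.5,
                     ifelse(species %in% sc$grouping$low, -0.5, 0))
  sp_eff <- sp_eff + outer(grp_eff, grp_sign)

  cls <- rep("none", n_genes)
  cls_species <- rep("", n_genes); cls_plants <- rep("", n_genes)
  direction <- rep("", n_genes)

  # planted classes live on shuffled catalog genes
  pool <- sample(which(is_detox))
  take <- function(n) {
    if (n == 0L) return(integer(0))
    out <- pool[seq_len(n)]
    if (anyNA(out)) ds_stop("simulate", "catalog too small for planted classes")
    pool <<- pool[-seq_len(n)]
    out
  }

  for (s in species) {
    for (d in c("over", "under")) {
      n <- if (d == "over") sc$n_constitutive_over else sc$n_constitutive_under
      idx <- take(n)
      shift <- if (d == "over") sc$constitutive_effect else -sc$constitutive_effect
      sp_eff[idx, s] <- sp_eff[idx, s] + shift
      cls[idx] <- "constitutive"
      cls_species[idx] <- s
      direction[idx] <- if (d == "over") "up" else "down"
    }
  }
  idx <- take(sc$n_plastic_single)
  for (g in idx) {
    s <- sample(species, 1L)
    pls <- sample(noncommon, sample(1:3, 1L))
    d <- sample(c("up", "down"), 1L)
    inter[g, s, pls] <- if (d == "up") sc$plastic_effect else -sc$plastic_effect
    cls[g] <- "plastic"
    cls_species[g] <- s
    cls_plants[g] <- paste(pls, collapse = ",")
    direction[g] <- d
  }
  plant_machinery <- function(n, group_species, d) {
    idx <- take(n)
    for (g in idx) {
      pls <- sample(noncommon, sample(2:3, 1L))
      eff <- if (d == "up") sc$machinery_effect else -sc$machinery_effect
      inter[g, group_species, pls] <<- eff
      cls[g] <<- "machinery"
      cls_species[g] <<- paste(group_species, collapse = ",")
      cls_plants[g] <<- paste(pls, collapse = ",")
      direction[g] <<- d
    }
  }
  plant_machinery(sc$n_machinery_induced, sc$grouping$high, "up")
  plant_machinery(sc$n_machinery_suppressed, sc$grouping$low, "down")

  lib <- runif(nrow(design), sc$lib_factor_range[1L], sc$lib_factor_range[2L])
  names(lib) <- design$sample_id

  counts <- matrix(0L, n_genes, nrow(design),
                   dimnames = list(gene_id, design$sample_id))
  si <- match(design$species, species)
  pi_ <- match(design$plant, plants)
  for (j in seq_len(nrow(design))) {
    eta <- base + sp_eff[, si[j]] + pl_eff[, pi_[j]] +
      inter[cbind(seq_len(n_genes), si[j], pi_[j])]
    counts[, j] <- as.integer(nb_draw(lib[j] * 2^eta, alpha))
  }

  genes <- data.frame(gene_id = gene_id, is_detox = is_detox, family = family,
                      class = cls, class_species = cls_species,
                      class_plants = cls_plants, direction = direction,
                      base_log2 = base, dispersion = alpha,
                      stringsAsFactors = FALSE)
  truth <- list(genes = genes, species_effects = sp_eff,
                plant_effects = pl_eff, interaction_effects = inter,
                group_effects = grp_eff, lib_factors = lib, scenario = sc)
  list(counts = counts, catalog = catalog, truth = truth, design = design)
}

#' Simulate binary character histories under the symmetric Mk model
#'
#' Each character starts at the root from `root_prior` and evolves along
#' every branch with change probability (1 - exp(-2 rate t))/2.
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @param rate non-negative transition rate.
#' @param n_char number of independent characters.
#' @param root_prior probabilities of states (0, 1) at the root.
#' @param seed integer seed.
#' @return list: `tip_states` (tips x characters 0/1 matrix, rownames = tip
#'   labels) and `node_states` ((tips + nodes) x characters true states).
#' @export
simulate_mk_history <- function(tree, rate, n_char = 1L,
                                root_prior = c(0.5, 0.5), seed = 1) {
  if (!is.numeric(rate) || rate < 0) ds_stop("simulate", "rate must be >= 0")
  stopifnot(length(root_prior) == 2L, all(root_prior >= 0),
            abs(sum(root_prior) - 1) < 1e-9)
  info <- tree_info(tree)
  set.seed(sub_seed(seed, "mk"))
  nn <- info$n + info$nnode
  states <- matrix(NA_integer_, nn, n_char)
  states[info$root, ] <- sample(0:1, n_char, replace = TRUE, prob = root_prior)
  for (v in rev(info$postorder)) {
    kids <- info$children[[v]]
    if (is.null(kids)) next
    for (k in kids) {
      pflip <- (1 - exp(-2 * rate * info$edge_len[k])) / 2
      flip <- runif(n_char) < pflip
      states[k, ] <- ifelse(flip, 1L - states[v, ], states[v, ])
    }
  }
  tips <- states[seq_len(info$n), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  list(tip_states = tips, node_states = states)
}

#' Simulate a survival assay
#'
#' Replicate survival proportions for every species x plant cell: either
#' plain binomial (`kappa = Inf`) or beta-binomial, where the per-replicate
#' survival probability is Beta(p kappa, (1 - p) kappa) around the true cell
#' mean p (smaller kappa = more between-replicate heterogeneity).
#'
#' @param true_p species x plant matrix of true survival probabilities.
#' @param n_rep replicates per cell (default 3).
#' @param n_adults adults per replicate group (default 50).
#' @param kappa beta concentration; Inf for plain binomial.
#' @param seed integer seed.
#' @return a [survival_table()].
#' @export
simulate_survival <- function(true_p, n_rep = 3L, n_adults = 50L,
                              kappa = Inf, seed = 1) {
  if (any(is.na(true_p)) || any(true_p < 0 | true_p > 1))
    ds_stop("simulate", "true survival probabilities must lie in [0, 1]")
  if (!is.infinite(kappa) && kappa <= 0)
    ds_stop("simulate", "kappa must be positive")
  set.seed(sub_seed(seed, "survival"))
  rows <- list()
  for (s in rownames(true_p)) for (pl in colnames(true_p)) {
    p <- true_p[s, pl]
    for (r in seq_len(n_rep)) {
      pr <- if (is.infinite(kappa) || p %in% c(0, 1)) p
            else rbeta(1L, p * kappa, (1 - p) * kappa)
      rows[[length(rows) + 1L]] <- data.frame(
        species = s, plant = pl, replicate = r,
        proportion_survived = rbinom(1L, n_adults, pr) / n_adults,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  survival_table(df$species, df$plant, df$replicate, df$proportion_survived)
}

#' Default true survival means of the six-species assay
#'
#' High survival for every species on the common host; on the noncommon
#' hosts the high-performance group keeps high survival while the
#' low-performance group drops.
#'
#' @param grouping a [performance_grouping()].
#' @param common,high_noncommon,low_noncommon cell means.
#' @return species x plant matrix of probabilities.
#' @export
default_survival_means <- function(grouping = default_grouping(),
                                   common = 0.9, high_noncommon = 0.75,
                                   low_noncommon = 0.4) {
  species <- c(grouping$high, grouping$low)
  m <- matrix(common, length(species), length(HOST_PLANTS),
              dimnames = list(species, HOST_PLANTS))
  nc <- setdiff(HOST_PLANTS, "eggplant")
  m[grouping$high, nc] <- high_noncommon
  m[grouping$low, nc] <- low_noncommon
  m
}
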