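#' Mean expression profiles per species x plant cell
#'
#' Collapses replicates: one column per design cell (24 in the default
#' 6 x 4 design), ordered species-major.
#'
#' @param expr gene x sample expression matrix (log2 scale).
#' @param design a [sample_design()] aligned with `expr` columns.
#' @return gene x cell matrix; columns named "species|plant".
#' @export
mean_profiles <- function(expr, design) {
  if (!identical(colnames(expr), design$sample_id))
    ds_stop("profiles", "expression columns do not match design")
  cells <- unique(design[, c("species", "plant")])
  cells <- cells[order(cells$species, match(cells$plant, HOST_PLANTS)), ]
  out <- matrix(NA_real_, nrow(expr), nrow(cells),
                dimnames = list(rownames(expr),
                                paste(cells$species, cells$plant, sep = "|")))
  for (i in seq_len(nrow(cells))) {
    idx <- design$species == cells$species[i] & design$plant == cells$plant[i]
    if (!any(idx)) ds_stop("profiles", "empty design cell")
    out[, i] <- rowMeans(expr[, idx, drop = FALSE])
  }
  out
}

#' Standardize each gene across profile columns
#'
#' Each row is centred and scaled to unit sample standard deviation (n - 1).
#' Zero-variance rows become all-zeros and are flagged in the
#' `zero_variance` attribute.
#'
#' @param profiles gene x cell matrix.
#' @return z-scored matrix with attribute `zero_variance` (logical vector).
#' @export
standardize_per_gene <- function(profiles) {
  if (ncol(profiles) < 2L) ds_stop("standardize", "need >= 2 columns")
  m <- rowMeans(profiles)
  s <- apply(profiles, 1L, sd)
  flat <- s == 0 | !is.finite(s)
  s[flat] <- 1
  out <- (profiles - m) / s
  out[flat, ] <- 0
  attr(out, "zero_variance") <- flat
  out
}

#' Pearson dissimilarity between profile columns
#'
#' d(i, j) = 1 - r(i, j) across genes; range [0, 2], zero diagonal.
#'
#' @param profiles gene x item matrix (items = columns).
#' @return symmetric dissimilarity matrix.
#' @export
pearson_dissimilarity <- function(profiles) {
  if (ncol(profiles) < 2L || nrow(profiles) < 2L)
    ds_stop("dissimilarity", "need >= 2 items and >= 2 genes")
  sds <- apply(profiles, 2L, sd)
  if (any(sds == 0))
    ds_stop("dissimilarity", "zero-variance column(s): ",
            paste(colnames(profiles)[sds == 0], collapse = ", "))
  d <- 1 - cor(profiles)
  diag(d) <- 0
  d
}

#' Does a profile dendrogram recover the performance grouping?
#'
#' Success requires (i) the plant profiles of every species to form a
#' contiguous subtree (a node whose leaf set is exactly that species'
#' cells), and (ii) the top split of the dendrogram to partition the species
#' into exactly the two performance groups.
#'
#' @param dend dendrogram from [hierarchical_cluster()] over species|plant
#'   profile columns (leaf labels "species|plant"), or over species means
#'   (leaf labels = species names).
#' @param grouping a [performance_grouping()].
#' @return TRUE or FALSE.
#' @export
bipartition_success <- function(dend, grouping) {
  stopifnot(inherits(grouping, "performance_grouping"))
  labs <- dend$labels
  leaf_species <- sub("\\|.*$", "", labs)
  species <- unique(leaf_species)
  missing <- setdiff(c(grouping$high, grouping$low), species)
  if (length(missing))
    ds_stop("clusternull", "grouping species not in dendrogram: ",
            paste(missing, collapse = ", "))
  sets <- dendrogram_leafsets(dend)
  # (i) species contiguity (only binding when a species has > 1 leaf)
  for (s in species) {
    mine <- sort(labs[leaf_species == s])
    if (length(mine) > 1L &&
        !any(vapply(sets, function(x) identical(x, mine), logical(1))))
      return(FALSE)
  }
  # (ii) top cut bipartition at the species level
  cut2 <- cut_into_k(dend, 2L)
  side1 <- unique(leaf_species[cut2 == 1L])
  side2 <- unique(leaf_species[cut2 == 2L])
  if (length(intersect(side1, side2))) return(FALSE)
  hi <- sort(grouping$high); lo <- sort(grouping$low)
  (identical(sort(side1), hi) && identical(sort(side2), lo)) ||
    (identical(sort(side1), lo) && identical(sort(side2), hi))
}

#' Random-gene-subset clustering null test
#'
#' Repeats the profile-clustering analysis `n_trials` times on random gene
#' subsets drawn without replacement from `pool`, counting how many trials
#' recover the performance grouping ([bipartition_success()]). Reports the
#' empirical p-value (successes + 1)/(trials + 1). Cell means and per-gene
#' standardization do not depend on which genes are subsampled, so they are
#' computed once up front.
#'
#' @param expr gene x sample expression matrix (log2 scale).
#' @param design a [sample_design()].
#' @param grouping a [performance_grouping()].
#' @param subset_size genes per trial (default 266).
#' @param n_trials number of trials (default 500).
#' @param seed master seed; each trial uses [sub_seed()].
#' @param pool gene ids to draw from (default: all rows of `expr`).
#' @param linkage linkage passed to [hierarchical_cluster()].
#' @return list of class `null_test_result`: `n_trials`, `subset_size`,
#'   `n_success`, `empirical_p`, `seed`, `criterion`.
#' @export
random_subset_null <- function(expr, design, grouping, subset_size = 266,
                               n_trials = 500, seed = 1,
                               pool = rownames(expr),
                               linkage = "complete") {
  pool <- intersect(pool, rownames(expr))
  if (length(pool) < subset_size)
    ds_stop("clusternull", sprintf("pool (%d) smaller than subset size (%d)",
                                   length(pool), subset_size))
  profiles <- mean_profiles(expr, design)
  std <- standardize_per_gene(profiles)
  n_success <- 0L
  for (trial in seq_len(max(n_trials, 0L))) {
    set.seed(sub_seed(seed, "nulltrial", trial))
    genes <- sample(pool, subset_size)
    ok <- tryCatch({
      d <- pearson_dissimilarity(std[genes, , drop = FALSE])
      bipartition_success(hierarchical_cluster(d, linkage), grouping)
    }, error = function(e) FALSE)
    if (ok) n_success <- n_success + 1L
  }
  structure(list(n_trials = as.integer(n_trials),
                 subset_size = as.integer(subset_size),
                 n_success = n_success,
                 empirical_p = (n_success + 1) / (n_trials + 1),
                 seed = seed,
                 criterion = "species-contiguous top-cut bipartition"),
            class = "null_test_result")
}

#' Correlation-matrix PCA of samples
#'
#' Principal components of the samples in gene space with the correlation
#' method: every gene is centred and scaled to unit variance before the
#' eigendecomposition, and eigenvectors are unit norm. Zero-variance genes
#' are dropped with a warning.
#'
#' @param expr gene x sample expression matrix.
#' @param design optional [sample_design()] bound to the scores for plotting.
#' @return list: `scores` (samples x components), `explained` (variance
#'   fractions summing to 1), `design`.
#' @export
pca_correlation <- function(expr, design = NULL) {
  if (ncol(expr) < 2L) ds_stop("pca", "need >= 2 samples")
  sds <- apply(expr, 1L, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance gene(s)", sum(sds == 0)))
    expr <- expr[sds > 0, , drop = FALSE]
  }
  pc <- prcomp(t(expr), center = TRUE, scale. = TRUE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, explained = explained, design = design)
}

#' Per-gene two-factor variance partition
#'
#' For every gene on a balanced species x plant design with replicates,
#' partitions the total sum of squares into species, plant, interaction and
#' residual components (the balanced-design identity makes the three effect
#' sums orthogonal). Also returns the mean fraction per component across
#' genes, the aggregate "sources of variation" summary.
#'
#' @param expr gene x sample expression matrix.
#' @param design a [sample_design()]; must be balanced.
#' @return list: `per_gene` (data.frame of SS fractions) and `aggregate`
#'   (named mean fractions).
#' @export
variance_partition <- function(expr, design) {
  if (!identical(colnames(expr), design$sample_id))
    ds_stop("anova", "expression columns do not match design")
  tab <- table(design$species, design$plant)
  if (length(unique(as.vector(tab))) != 1L || any(tab == 0))
    ds_stop("anova", "design must be balanced with equal replicates per cell")
  r <- as.vector(tab)[1L]
  sp <- factor(design$species); pl <- factor(design$plant)
  N <- ncol(expr)
  grand <- rowMeans(expr)
  sp_means <- vapply(levels(sp), function(s)
    rowMeans(expr[, sp == s, drop = FALSE]), numeric(nrow(expr)))
  pl_means <- vapply(levels(pl), function(p)
    rowMeans(expr[, pl == p, drop = FALSE]), numeric(nrow(expr)))
  cells <- expand.grid(species = levels(sp), plant = levels(pl),
                       stringsAsFactors = FALSE)
  cell_means <- vapply(seq_len(nrow(cells)), function(i)
    rowMeans(expr[, sp == cells$species[i] & pl == cells$plant[i],
                  drop = FALSE]), numeric(nrow(expr)))
  ss_species <- rowSums((sp_means - grand)^2) * r * nlevels(pl)
  ss_plant <- rowSums((pl_means - grand)^2) * r * nlevels(sp)
  # interaction: cell mean minus additive expectation
  add <- sp_means[, cells$species, drop = FALSE] +
    pl_means[, cells$plant, drop = FALSE] - grand
  ss_inter <- rowSums((cell_means - add)^2) * r
  sample_cell <- match(paste(design$species, design$plant),
                       paste(cells$species, cells$plant))
  fitted <- cell_means[, sample_cell, drop = FALSE]
  ss_resid <- rowSums((expr - fitted)^2)
  ss_total <- rowSums((expr - grand)^2)
  frac <- data.frame(gene_id = rownames(expr),
                     species = ss_species / ss_total,
                     plant = ss_plant / ss_total,
                     interaction = ss_inter / ss_total,
                     residual = ss_resid / ss_total,
                     ss_total = ss_total, stringsAsFactors = FALSE)
  ok <- ss_total > 0
  agg <- colMeans(frac[ok, c("species", "plant", "interaction", "residual")])
  list(per_gene = frac, aggregate = agg)
}
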