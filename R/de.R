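#' Filter genes with too few reads in too few samples
#'
#' A gene is retained when it has at least `min_reads` reads in at least
#' `ceiling(sample_fraction * n_samples)` samples. The retained count is
#' logged, matching the audit trail expression pipelines usually keep.
#'
#' @param counts gene x sample count matrix.
#' @param min_reads minimum reads per sample to count that sample.
#' @param sample_fraction fraction of samples required, in (0, 1].
#' @return the filtered count matrix (possibly zero rows, with a warning).
#' @export
filter_low_counts <- function(counts, min_reads = 10, sample_fraction = 0.04) {
  stopifnot(min_reads >= 0, sample_fraction > 0, sample_fraction <= 1)
  need <- ceiling(sample_fraction * ncol(counts))
  keep <- rowSums(counts >= min_reads) >= need
  out <- counts[keep, , drop = FALSE]
  ds_log("filter_low_counts: kept %d of %d genes (>= %g reads in >= %d samples)",
         nrow(out), nrow(counts), min_reads, need)
  if (nrow(out) == 0L) warning("all genes filtered out")
  out
}

#' Median-of-ratios size factors
#'
#' The standard RNA-seq normalization: each sample's factor is the median,
#' over genes with all-positive counts, of the ratio of the sample's count to
#' the gene's geometric mean. Factors are rescaled to geometric mean 1
#' (ratios between samples are unchanged).
#'
#' @param counts gene x sample count matrix.
#' @return positive numeric vector of per-sample factors.
#' @export
size_factors_median_ratio <- function(counts) {
  pos <- rowSums(counts <= 0) == 0L
  if (!any(pos))
    ds_stop("normalize",
            "no gene with all-positive counts; add a pseudocount upstream")
  lc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(lc)
  sf <- apply(exp(lc - loggeo), 2L, median)
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Method-of-moments per-gene NB dispersion
#'
#' Within every design cell (species x plant) with >= 2 replicates, the
#' dispersion of normalized counts is estimated as (s^2 - mean)/mean^2 and
#' pooled across cells weighted by within-cell degrees of freedom. With
#' `prior_df > 0` (the default) the per-gene estimate is moderated toward
#' the across-gene median, the usual empirical-Bayes stabilization that
#' keeps downstream Wald tests from being driven by underestimated
#' dispersions at small replicate numbers. Estimates are floored at 1e-8
#' (Poisson-like genes land on the floor).
#'
#' @param counts gene x sample count matrix.
#' @param size_factors per-sample factors from [size_factors_median_ratio()].
#' @param design a [sample_design()] aligned with `counts` columns.
#' @param floor minimum dispersion.
#' @param prior_df weight (in pseudo-degrees-of-freedom) of the across-gene
#'   median in the moderated estimate; 0 disables moderation.
#' @return numeric vector of per-gene dispersions alpha (Var = mu + alpha mu^2).
#' @export
estimate_dispersion <- function(counts, size_factors, design, floor = 1e-8,
                                prior_df = 50) {
  norm <- sweep(counts, 2L, size_factors, "/")
  cell <- interaction(design$species, design$plant, drop = TRUE)
  cells <- split(seq_len(ncol(norm)), cell)
  cells <- cells[lengths(cells) >= 2L]
  if (length(cells) == 0L)
    ds_stop("dispersion", "no design cell has >= 2 replicates")
  num <- rep(0, nrow(norm)); den <- rep(0, nrow(norm))
  for (idx in cells) {
    sub <- norm[, idx, drop = FALSE]
    m <- rowMeans(sub)
    v <- (rowSums(sub^2) - length(idx) * m^2) / (length(idx) - 1L)
    v <- pmax(v, 0)
    ok <- m > 0
    a <- ifelse(ok, (v - m) / pmax(m, 1e-12)^2, NA_real_)
    w <- length(idx) - 1L
    num <- num + ifelse(ok, w * a, 0)
    den <- den + ifelse(ok, w, 0)
  }
  alpha <- ifelse(den > 0, num / den, floor)
  if (prior_df > 0 && length(alpha) > 1L) {
    center <- median(pmax(alpha, 0))
    alpha <- (den * alpha + prior_df * center) / (den + prior_df)
  }
  alpha <- pmax(alpha, floor)
  names(alpha) <- rownames(counts)
  alpha
}

#' Negative-binomial Wald test for one contrast
#'
#' Per-gene log2 fold change between two groups of samples computed on
#' normalized counts with a pseudo-mean, with a delta-method standard error
#' from the NB variance (Var(k/s) = mu/s + alpha mu^2) and a two-sided Wald
#' p-value against the normal reference.
#'
#' @param counts gene x sample count matrix.
#' @param size_factors per-sample factors.
#' @param dispersions per-gene alpha (recycled if scalar).
#' @param samples_a,samples_b column names (or indices) of the two groups;
#'   the reported log2 fold change is B relative to A.
#' @param contrast label stored in the result (default "B_vs_A").
#' @param pseudo_mean pseudo-mean added inside the fold change (default 0.5).
#' @return data.frame `gene_id`, `contrast`, `log2fc`, `p` (no adjustment).
#' @export
nb_wald_test <- function(counts, size_factors, dispersions,
                         samples_a, samples_b, contrast = "B_vs_A",
                         pseudo_mean = 0.5) {
  if (length(samples_a) == 0L || length(samples_b) == 0L)
    ds_stop("de", "empty contrast cell")
  alpha <- rep_len(dispersions, nrow(counts))
  ka <- counts[, samples_a, drop = FALSE]
  kb <- counts[, samples_b, drop = FALSE]
  sa <- size_factors[samples_a]; sb <- size_factors[samples_b]
  na <- length(samples_a); nb <- length(samples_b)
  ma <- rowMeans(sweep(ka, 2L, sa, "/"))
  mb <- rowMeans(sweep(kb, 2L, sb, "/"))
  lfc <- log2((mb + pseudo_mean) / (ma + pseudo_mean))
  # Var of a group mean of normalized counts, NB variance per sample
  va <- rowSums(ma %o% (1 / sa) + alpha * ma^2) / na^2
  vb <- rowSums(mb %o% (1 / sb) + alpha * mb^2) / nb^2
  ln2 <- log(2)
  se <- sqrt(va / (ma + pseudo_mean)^2 + vb / (mb + pseudo_mean)^2) / ln2
  z <- ifelse(se > 0, lfc / se, 0)
  p <- ifelse(lfc == 0, 1, 2 * pnorm(-abs(z)))
  data.frame(gene_id = rownames(counts), contrast = contrast,
             log2fc = lfc, p = pmin(p, 1), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control across all retained genes of one contrast.
#'
#' @param p vector of p-values in [0, 1]; NA is an error.
#' @return adjusted p-values, capped at 1.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p))) ds_stop("de", "NA/NaN p-value")
  if (any(p < 0 | p > 1)) ds_stop("de", "p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Shifted-log2 expression transform
#'
#' log2(normalized count + pseudocount): a monotone log2-scale stand-in for
#' regularized-log style transforms, used for clustering, PCA and ANOVA.
#'
#' @param counts gene x sample count matrix.
#' @param size_factors per-sample positive factors.
#' @param pseudocount added before the log (default 1).
#' @return finite numeric matrix, same dimensions as `counts`.
#' @export
regularized_log <- function(counts, size_factors, pseudocount = 1) {
  if (any(size_factors <= 0)) ds_stop("rlog", "size factors must be positive")
  log2(sweep(counts, 2L, size_factors, "/") + pseudocount)
}

#' Call differential expression at fold-change and FDR thresholds
#'
#' A gene is called when |log2FC| >= `lfc_threshold` and padj <= `padj_threshold`;
#' calls are tagged "up"/"down" by the sign of the fold change.
#'
#' @param results data.frame with columns `log2fc` and `padj`.
#' @param lfc_threshold absolute log2 fold-change threshold (1 for
#'   constitutive between-species contrasts, 0.58 for plastic within-species
#'   contrasts).
#' @param padj_threshold adjusted-p threshold (default 0.05).
#' @return `results` with an added `call` column in c("up", "down", "ns").
#' @export
call_de <- function(results, lfc_threshold, padj_threshold = 0.05) {
  stopifnot(lfc_threshold > 0, padj_threshold > 0)
  sig <- abs(results$log2fc) >= lfc_threshold & results$padj <= padj_threshold
  results$call <- ifelse(sig & results$log2fc > 0, "up",
                         ifelse(sig, "down", "ns"))
  results
}

# internal: sample ids of one (species, plant) cell
cell_samples <- function(design, species, plant) {
  design$sample_id[design$species == species & design$plant == plant]
}

#' All between-species contrasts on the common host
#'
#' Runs the NB Wald test for every unordered species pair on the baseline
#' plant and adjusts p-values per contrast across all genes. The log2 fold
#' change of contrast "S2_vs_S1" is S2 relative to S1.
#'
#' @param counts,size_factors,dispersions,design as in [nb_wald_test()].
#' @param plant baseline plant (default "eggplant").
#' @return data.frame of stacked [nb_wald_test()] results with `species_a`,
#'   `species_b` and `padj` columns.
#' @export
de_between_species <- function(counts, size_factors, dispersions, design,
                               plant = "eggplant") {
  sp <- sort(unique(design$species))
  out <- list()
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (j <= i) next
    a <- cell_samples(design, sp[i], plant)
    b <- cell_samples(design, sp[j], plant)
    res <- nb_wald_test(counts, size_factors, dispersions, a, b,
                        contrast = sprintf("%s_vs_%s", sp[j], sp[i]))
    res$species_a <- sp[i]; res$species_b <- sp[j]
    res$padj <- adjust_bh(res$p)
    out[[length(out) + 1L]] <- res
  }
  do.call(rbind, out)
}

#' All within-species plastic contrasts against the common host
#'
#' For every species, tests each noncommon plant against the baseline plant.
#' The log2 fold change is noncommon plant relative to baseline.
#'
#' @param counts,size_factors,dispersions,design as in [nb_wald_test()].
#' @param baseline common-host plant (default "eggplant").
#' @return data.frame with `species`, `plant`, `padj` columns added.
#' @export
de_within_species <- function(counts, size_factors, dispersions, design,
                              baseline = "eggplant") {
  sp <- sort(unique(design$species))
  plants <- setdiff(unique(design$plant), baseline)
  out <- list()
  for (s in sp) for (p in plants) {
    a <- cell_samples(design, s, baseline)
    b <- cell_samples(design, s, p)
    res <- nb_wald_test(counts, size_factors, dispersions, a, b,
                        contrast = sprintf("%s:%s_vs_%s", s, p, baseline))
    res$species <- s; res$plant <- p
    res$padj <- adjust_bh(res$p)
    out[[length(out) + 1L]] <- res
  }
  do.call(rbind, out)
}
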