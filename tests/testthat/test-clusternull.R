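# profiles engineered at the species x plant level; labels "species|plant"
make_profiles <- function(species, group_of, n_genes = 200, group_sd = 1,
                          species_sd = 2, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  g_shift <- list(H = rnorm(n_genes, 0, group_sd),
                  L = -rnorm(n_genes, 0, group_sd))
  cols <- list()
  for (s in species) {
    v <- rnorm(n_genes, 0, species_sd) + g_shift[[group_of[s]]]
    for (p in HOST_PLANTS)
      cols[[paste(s, p, sep = "|")]] <- v + rnorm(n_genes, 0, noise_sd)
  }
  do.call(cbind, cols)
}

test_that("cell-mean profiles reproduce a brute-force group-by", {
  design <- default_design(species = c("A", "B"), n_rep = 3)
  set.seed(121)
  expr <- matrix(rnorm(20 * nrow(design)), 20, nrow(design),
                 dimnames = list(paste0("g", 1:20), design$sample_id))
  prof <- mean_profiles(expr, design)
  expect_equal(ncol(prof), 8)
  for (cell in colnames(prof)) {
    parts <- strsplit(cell, "|", fixed = TRUE)[[1]]
    idx <- design$species == parts[1] & design$plant == parts[2]
    expect_equal(prof[, cell], rowMeans(expr[, idx]))
  }
  # identical replicates pass through; (1,2,3) averages to 2
  expr[1, design$species == "A" & design$plant == "kale"] <- c(1, 2, 3)
  expect_equal(unname(mean_profiles(expr, design)[1, "A|kale"]), 2)
})

test_that("per-gene standardization yields unit rows and flags flat genes", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(-2, 0, 4))
  z <- standardize_per_gene(m)
  expect_equal(unname(rowMeans(z)), rep(0, 3))
  expect_equal(unname(apply(z[c("a", "c"), ], 1, sd)), c(1, 1))
  expect_equal(unname(z["b", ]), rep(0, 3))
  expect_equal(unname(attr(z, "zero_variance")), c(FALSE, TRUE, FALSE))
  # affine invariance
  z2 <- standardize_per_gene(3 * m + 7)
  expect_equal(unname(z2), unname(z))
})

test_that("Pearson dissimilarity spans [0, 2] and matches the direct formula", {
  set.seed(131)
  x <- rnorm(50)
  m <- cbind(a = x, b = x, c = -x)
  d <- pearson_dissimilarity(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  r <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, letters[1:4]))
  dr <- pearson_dissimilarity(r)
  for (i in letters[1:3]) for (j in letters[2:4])
    expect_equal(dr[i, j], 1 - cor(r[, i], r[, j]))
  bad <- cbind(a = x, flat = rep(1, 50))
  expect_error(pearson_dissimilarity(bad), "zero-variance")
})

test_that("bipartition success needs species contiguity plus the exact top split", {
  grouping <- performance_grouping(high = c("S1", "S2", "S3"),
                                   low = c("S4", "S5", "S6"))
  gof <- setNames(c("H", "H", "H", "L", "L", "L"), paste0("S", 1:6))
  good <- make_profiles(paste0("S", 1:6), gof, seed = 5)
  dend <- hierarchical_cluster(pearson_dissimilarity(standardize_per_gene(good)))
  expect_true(bipartition_success(dend, grouping))

  # wrong grouping hypothesis fails on the same dendrogram
  expect_false(bipartition_success(dend,
    performance_grouping(high = c("S1", "S2", "S4"), low = c("S3", "S5", "S6"))))

  # tearing one species' eggplant profile into the other group breaks contiguity
  torn <- good
  torn[, "S1|eggplant"] <- good[, "S4|eggplant"]
  dend2 <- hierarchical_cluster(pearson_dissimilarity(standardize_per_gene(torn)))
  expect_false(bipartition_success(dend2, grouping))

  expect_error(bipartition_success(dend,
    performance_grouping(high = "S9", low = paste0("S", 1:6))),
    "not in dendrogram")
})

test_that("the random-subset null is deterministic, bounded and counts honestly", {
  design <- default_design(species = paste0("S", 1:6), n_rep = 2)
  grouping <- performance_grouping(paste0("S", 1:3), paste0("S", 4:6))
  set.seed(141)
  expr <- matrix(rnorm(400 * nrow(design)), 400, nrow(design),
                 dimnames = list(paste0("g", 1:400), design$sample_id))
  r0 <- random_subset_null(expr, design, grouping, subset_size = 50,
                           n_trials = 0, seed = 9)
  expect_equal(r0$n_success, 0L)
  expect_equal(r0$empirical_p, 1)

  r1 <- random_subset_null(expr, design, grouping, subset_size = 50,
                           n_trials = 5, seed = 9)
  r2 <- random_subset_null(expr, design, grouping, subset_size = 50,
                           n_trials = 5, seed = 9)
  expect_identical(r1, r2)
  expect_true(r1$n_success >= 0 && r1$n_success <= r1$n_trials)

  expect_error(random_subset_null(expr, design, grouping, subset_size = 500,
                                  n_trials = 5, seed = 1), "smaller than")
})

test_that("catalog-pool trials recover the grouping; pure-noise trials do not", {
  design <- default_design()
  grouping <- default_grouping()
  sim <- simulate_counts(design, small_scenario(1500), seed = 4)
  prep <- de_prep(sim)
  cat_pool <- intersect(sim$catalog$gene_id, rownames(prep$rld))
  pos <- random_subset_null(prep$rld, design, grouping, subset_size = 200,
                            n_trials = 10, seed = 4, pool = cat_pool)
  expect_equal(pos$n_success, pos$n_trials)

  bg_pool <- setdiff(rownames(prep$rld), sim$catalog$gene_id)
  neg <- random_subset_null(prep$rld, design, grouping, subset_size = 200,
                            n_trials = 25, seed = 4, pool = bg_pool)
  expect_equal(neg$n_success, 0L)
})

test_that("correlation PCA yields unit-sum variance fractions and orthogonal scores", {
  set.seed(151)
  expr <- matrix(rnorm(100 * 12), 100, 12,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:12)))
  # planted dominant axis separating two sample halves
  expr[1:60, 1:6] <- expr[1:60, 1:6] + 4
  expr <- rbind(expr, flat = rep(1, 12))
  expect_warning(pc <- pca_correlation(expr), "zero-variance")
  expect_equal(sum(pc$explained), 1, tolerance = 1e-10)
  expect_gt(pc$explained[1], 0.5)
  gram <- crossprod(pc$scores)
  expect_equal(unname(gram - diag(diag(gram))),
               matrix(0, ncol(gram), ncol(gram)), tolerance = 1e-8)
})

test_that("the two-factor variance partition matches aov and sums exactly", {
  design <- default_design(species = c("A", "B", "C"), n_rep = 3)
  set.seed(161)
  expr <- matrix(rnorm(12 * nrow(design)), 12, nrow(design),
                 dimnames = list(paste0("g", 1:12), design$sample_id))
  # gene 1 varies only by species
  sp_mean <- setNames(c(0, 5, 10), c("A", "B", "C"))
  expr[1, ] <- sp_mean[design$species]
  vp <- variance_partition(expr, design)
  expect_equal(vp$per_gene$species[1], 1)
  expect_equal(vp$per_gene$residual[1], 0)

  # decomposition identity and equality with aov sums of squares
  fr <- vp$per_gene
  expect_equal(fr$species + fr$plant + fr$interaction + fr$residual,
               rep(1, 12), tolerance = 1e-9)
  for (g in 2:4) {
    fit <- aov(expr[g, ] ~ factor(design$species) * factor(design$plant))
    ss <- summary(fit)[[1]][, "Sum Sq"]
    expect_equal(fr$species[g] * fr$ss_total[g], ss[1], tolerance = 1e-9)
    expect_equal(fr$plant[g] * fr$ss_total[g], ss[2], tolerance = 1e-9)
    expect_equal(fr$interaction[g] * fr$ss_total[g], ss[3], tolerance = 1e-9)
    expect_equal(fr$residual[g] * fr$ss_total[g], ss[4], tolerance = 1e-9)
  }

  unbal <- design[-1, ]
  expect_error(variance_partition(expr[, -1], unbal), "balanced")
})
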