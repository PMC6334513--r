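test_that("low-count filter applies the ceiling rule on the sample fraction", {
  n <- 72  # ceil(0.04 * 72) = 3 samples required
  mk <- function(k) c(rep(10L, k), rep(0L, n - k))
  counts <- rbind(in3 = mk(3), in2 = mk(2), zero = rep(0L, n),
                  all10 = rep(10L, n))
  colnames(counts) <- paste0("s", 1:n)
  kept <- rownames(filter_low_counts(counts))
  expect_true("in3" %in% kept)
  expect_false("in2" %in% kept)
  expect_false("zero" %in% kept)
  expect_true("all10" %in% kept)
})

test_that("median-of-ratios factors are scale- and permutation-equivariant", {
  set.seed(61)
  counts <- matrix(rnbinom(50 * 4, mu = 100, size = 10) + 1L, 50, 4,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  # identical columns -> all factors 1
  same <- counts[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(size_factors_median_ratio(same)), rep(1, 3))

  # doubling one column doubles its factor relative to the rest
  doubled <- cbind(counts, s5 = 2L * counts[, 1])
  sf <- size_factors_median_ratio(doubled)
  expect_equal(unname(sf["s5"] / sf["s1"]), 2, tolerance = 1e-12)

  # matches the direct median-of-ratios definition up to the geomean-1 rescale
  oracle <- apply(counts, 2, function(col)
    median(col / exp(rowMeans(log(counts)))))
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(size_factors_median_ratio(counts), oracle)
  expect_equal(exp(mean(log(size_factors_median_ratio(counts)))), 1)

  perm <- sample(4)
  expect_equal(size_factors_median_ratio(counts[, perm]),
               size_factors_median_ratio(counts)[perm])

  zeros <- matrix(0L, 3, 2, dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_error(size_factors_median_ratio(zeros), "pseudocount")
})

test_that("hand-computed 5x4 fixture reproduces the medians of ratios", {
  counts <- matrix(c(10, 20, 30, 40,
                     100, 100, 100, 100,
                     5, 10, 5, 10,
                     50, 25, 75, 100,
                     8, 8, 16, 8), 5, 4, byrow = TRUE,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  geo <- apply(counts, 1, function(r) exp(mean(log(r))))
  expected <- apply(sweep(counts, 1, geo, "/"), 2, median)
  expected <- expected / exp(mean(log(expected)))
  expect_equal(size_factors_median_ratio(counts), expected)
})

test_that("moment dispersion estimates land on the floor for clean data and near truth for NB", {
  des <- sample_design(paste0("s", 1:24), rep("spA", 24),
                       rep(HOST_PLANTS, each = 6), rep(1:6, 4))
  sfu <- setNames(rep(1, 24), des$sample_id)

  # constant counts within cells -> floor
  counts <- matrix(7L, 10, 24, dimnames = list(paste0("g", 1:10), des$sample_id))
  a <- estimate_dispersion(counts, sfu, des, prior_df = 0)
  expect_equal(unname(a), rep(1e-8, 10))

  # Poisson data -> median near the floor side of zero
  set.seed(71)
  pois <- matrix(rpois(2000 * 24, 100), 2000, 24,
                 dimnames = list(paste0("g", 1:2000), des$sample_id))
  ap <- estimate_dispersion(pois, sfu, des, prior_df = 0)
  expect_lt(median(ap), 0.005)

  # NB alpha = 0.2 with 6 replicates x 4 cells
  nb <- matrix(rnbinom(2000 * 24, mu = 200, size = 1 / 0.2), 2000, 24,
               dimnames = list(paste0("g", 1:2000), des$sample_id))
  an <- estimate_dispersion(nb, sfu, des, prior_df = 0)
  expect_gt(median(an), 0.1)
  expect_lt(median(an), 0.3)

  single <- sample_design(c("x", "y"), c("A", "A"), c("eggplant", "kale"),
                          c(1L, 1L))
  m <- matrix(1L, 2, 2, dimnames = list(c("g1", "g2"), c("x", "y")))
  expect_error(estimate_dispersion(m, c(x = 1, y = 1), single), "replicates")
})

test_that("the NB Wald test is exact on identical groups and recovers planted effects", {
  counts <- matrix(rep(c(10L, 40L, 90L), each = 6), 3, 6, byrow = TRUE,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  sfu <- setNames(rep(1, 6), colnames(counts))
  res <- nb_wald_test(counts, sfu, 0.1, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  expect_error(nb_wald_test(counts, sfu, 0.1, character(0), "s1"), "empty")

  set.seed(81)
  n <- 2000
  mu <- 2^runif(n, 5, 9)
  ca <- matrix(rnbinom(n * 3, mu = mu, size = 1 / 0.05), n, 3)
  cb <- matrix(rnbinom(n * 3, mu = 4 * mu, size = 1 / 0.05), n, 3)
  counts <- cbind(ca, cb)
  dimnames(counts) <- list(paste0("g", 1:n), paste0("s", 1:6))
  res <- nb_wald_test(counts, setNames(rep(1, 6), colnames(counts)), 0.05,
                      paste0("s", 1:3), paste0("s", 4:6))
  expect_lt(abs(median(res$log2fc) - 2), 0.3)
})

test_that("BH adjustment matches the hand-applied step-up", {
  expect_equal(adjust_bh(0.42), 0.42)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.1, NA)), "NA")
  expect_error(adjust_bh(c(0.1, 1.4)), "outside")
})

test_that("the log2 transform hits its anchor points and scales with factors", {
  counts <- matrix(c(0L, 7L), 1, 2, dimnames = list("g", c("a", "b")))
  r <- regularized_log(counts, c(a = 1, b = 1))
  expect_equal(unname(r[1, ]), c(0, 3))
  r2 <- regularized_log(counts, c(a = 1, b = 2))
  expect_equal(unname(r2[1, "b"]), log2(7 / 2 + 1))
  expect_error(regularized_log(counts, c(a = 0, b = 1)), "positive")
})

test_that("DE calls honor both thresholds with direction tags", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    log2fc = c(0.9, 0.6, -1.2),
                    padj = c(0.01, 0.04, 0.2))
  expect_equal(call_de(res, 1)$call, c("ns", "ns", "ns"))
  expect_equal(call_de(res, 0.58)$call, c("up", "up", "ns"))
  res2 <- data.frame(gene_id = "d", log2fc = -2, padj = 0.001)
  expect_equal(call_de(res2, 1)$call, "down")
})

test_that("contrast builders cover every pair and orient fold changes", {
  set.seed(91)
  design <- default_design(species = c("A", "B", "C"), n_rep = 2)
  counts <- matrix(rnbinom(100 * nrow(design), mu = 50, size = 20) + 1L,
                   100, nrow(design),
                   dimnames = list(paste0("g", 1:100), design$sample_id))
  sf <- size_factors_median_ratio(counts)
  between <- de_between_species(counts, sf, 0.05, design)
  expect_equal(sort(unique(between$contrast)),
               c("B_vs_A", "C_vs_A", "C_vs_B"))
  expect_equal(nrow(between), 300)
  within <- de_within_species(counts, sf, 0.05, design)
  expect_equal(length(unique(within$contrast)), 9)  # 3 species x 3 plants
  expect_true(all(within$plant != "eggplant"))
})
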