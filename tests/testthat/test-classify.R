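# builders for synthetic DE tables covering a full contrast grid
make_between <- function(species, genes) {
  prs <- t(combn(sort(species), 2))
  out <- expand.grid(gene_id = genes, k = seq_len(nrow(prs)),
                     stringsAsFactors = FALSE)
  out$species_a <- prs[out$k, 1]
  out$species_b <- prs[out$k, 2]
  out$contrast <- sprintf("%s_vs_%s", out$species_b, out$species_a)
  out$log2fc <- 0
  out$padj <- 1
  out$k <- NULL
  out
}
make_within <- function(species, plants, genes) {
  out <- expand.grid(gene_id = genes, species = sort(species),
                     plant = sort(plants), stringsAsFactors = FALSE)
  out$contrast <- sprintf("%s:%s_vs_eggplant", out$species, out$plant)
  out$log2fc <- 0
  out$padj <- 1
  out
}
set_between <- function(df, gene, sp, lfc, padj = 0.001) {
  # gene expressed at lfc in species sp relative to every other species
  hit_b <- df$gene_id == gene & df$species_b == sp
  hit_a <- df$gene_id == gene & df$species_a == sp
  df$log2fc[hit_b] <- lfc
  df$log2fc[hit_a] <- -lfc
  df$padj[hit_a | hit_b] <- padj
  df
}
set_within <- function(df, gene, sp, plant, lfc, padj = 0.001) {
  hit <- df$gene_id == gene & df$species == sp & df$plant == plant
  df$log2fc[hit] <- lfc
  df$padj[hit] <- padj
  df
}

SP <- c("A", "B", "C", "D", "E", "F")
NC <- c("cassava", "kale", "pepper")

test_that("constitutive uniqueness requires beating every other species", {
  df <- make_between(SP, c("g1", "g2", "g3"))
  df <- set_between(df, "g1", "A", 2)             # unique over in A
  df <- set_between(df, "g3", "B", -1.5)          # unique under in B
  # g2: higher than 4 others but fails against F
  df <- set_between(df, "g2", "C", 2)
  miss <- df$gene_id == "g2" & ((df$species_a == "C" & df$species_b == "F") |
                                (df$species_a == "F" & df$species_b == "C"))
  df$padj[miss] <- 0.9
  res <- constitutive_unique(df)
  expect_equal(res$A$over, "g1")
  expect_equal(res$B$under, "g3")
  expect_length(res$C$over, 0)
  # no gene is unique to two species, or over and under at once
  all_over <- unlist(lapply(res, `[[`, "over"))
  expect_false(any(duplicated(all_over)))

  empty <- constitutive_unique(df[0, ])
  expect_true(all(lengths(unlist(empty, recursive = FALSE)) == 0))

  expect_error(constitutive_unique(df[!(df$species_a == "A" & df$species_b == "B"), ]),
               "missing between-species contrast")
})

test_that("plastic sets split by plant and the pattern classes follow the counts", {
  genes <- sprintf("g%03d", 1:120)
  df <- make_within(SP, NC, genes)
  # A: 30 genes on cassava + 25 on pepper -> multi-host-high
  for (g in genes[1:30]) df <- set_within(df, g, "A", "cassava", 1)
  for (g in genes[6:30]) df <- set_within(df, g, "A", "pepper", -1)
  # B: 30 genes on kale only -> single-host-high
  for (g in genes[31:60]) df <- set_within(df, g, "B", "kale", 0.8)
  # C: 5 genes on cassava -> low
  for (g in genes[61:65]) df <- set_within(df, g, "C", "cassava", 2)
  ps <- plastic_sets(df)
  expect_equal(unname(ps$pattern[c("A", "B", "C", "D")]),
               c("multi-host-high", "single-host-high", "low", "low"))
  expect_length(ps$sets$A$cassava$up, 30)
  expect_length(ps$sets$A$pepper$down, 25)
  expect_length(ps$sets$B$kale$up, 30)

  # sub-threshold fold change or padj is not called
  df2 <- make_within(SP, NC, "h1")
  df2 <- set_within(df2, "h1", "A", "cassava", 0.5)
  expect_length(plastic_sets(df2)$sets$A$cassava$up, 0)

  expect_error(plastic_sets(df[df$plant != "kale" | df$species != "F", ]),
               "missing contrast")
})

test_that("machinery keeps only direction-consistent multi-species genes", {
  df <- make_within(SP, NC, c("m1", "m2", "m3"))
  df <- set_within(df, "m1", "A", "cassava", 1)   # up in A and B -> machinery
  df <- set_within(df, "m1", "B", "cassava", 1.2)
  df <- set_within(df, "m2", "A", "kale", 1)      # up in A, down in B only
  df <- set_within(df, "m2", "B", "kale", -1)
  df <- set_within(df, "m3", "A", "pepper", 2)    # single species
  sh <- shared_machinery(plastic_sets(df))
  expect_setequal(sh$shared_multi, c("m1", "m2"))
  expect_equal(sh$machinery, "m1")
})

test_that("machinery is equivariant under species relabelling", {
  df <- make_within(SP, NC, c("m1", "m2"))
  df <- set_within(df, "m1", "A", "cassava", 1)
  df <- set_within(df, "m1", "C", "kale", 0.7)
  df <- set_within(df, "m2", "B", "kale", -2)
  df <- set_within(df, "m2", "D", "pepper", -1)
  ref <- shared_machinery(plastic_sets(df))$machinery
  perm <- setNames(SP[c(3, 1, 2, 6, 4, 5)], SP)
  df2 <- df
  df2$species <- unname(perm[df$species])
  df2$contrast <- sprintf("%s:%s_vs_eggplant", df2$species, df2$plant)
  expect_equal(shared_machinery(plastic_sets(df2))$machinery, ref)
})

test_that("family enrichment is the direct chi-squared against catalog proportions", {
  fam_counts <- c(P450 = 104, GST = 25, COE = 24, UDPGT = 71,
                  SULT = 20, ABC = 54)
  cat_ <- gene_catalog(sprintf("g%03d", 1:298),
                       rep(names(fam_counts), fam_counts))

  # proportions identical to the catalog -> chi2 = 0, p = 1
  res0 <- family_enrichment(cat_$gene_id, cat_)
  expect_equal(res0$chi_square, 0)
  expect_equal(res0$p, 1)
  expect_equal(res0$df, 5)

  # 60-gene fixture with observed counts (30, 5, 5, 15, 2, 3)
  want <- c(P450 = 30, GST = 5, COE = 5, UDPGT = 15, SULT = 2, ABC = 3)
  genes <- unlist(lapply(names(want), function(f)
    head(cat_$gene_id[cat_$family == f], want[f])))
  res <- family_enrichment(genes, cat_)
  expd <- fam_counts / 298 * 60
  obs <- want[DETOX_FAMILIES]
  expect_equal(res$chi_square, sum((obs - expd[DETOX_FAMILIES])^2 /
                                   expd[DETOX_FAMILIES]))
  expect_equal(res$p, pchisq(res$chi_square, 5, lower.tail = FALSE))

  expect_error(family_enrichment(c("g001", "nope"), cat_), "not in catalog")

  # fuzzed sets against the direct formula
  set.seed(111)
  for (rep in 1:50) {
    s <- sample(cat_$gene_id, sample(5:150, 1))
    r <- family_enrichment(s, cat_)
    fam <- cat_$family[match(s, cat_$gene_id)]
    o <- as.vector(table(factor(fam, levels = DETOX_FAMILIES)))
    e <- fam_counts / 298 * length(s)
    expect_equal(r$chi_square, sum((o - e)^2 / e), tolerance = 1e-12)
  }
})

test_that("the classification report restricts to the catalog universe", {
  cat_ <- gene_catalog(c("d1", "d2"), c("P450", "GST"))
  genes <- c("d1", "d2", "bg1")
  between <- make_between(SP, genes)
  within <- make_within(SP, NC, genes)
  between <- set_between(between, "d1", "A", 2)
  between <- set_between(between, "bg1", "B", 2)  # background: must be ignored
  within <- set_within(within, "d2", "A", "kale", 1)
  within <- set_within(within, "d2", "B", "kale", 1)
  within <- set_within(within, "bg1", "A", "kale", 1)
  within <- set_within(within, "bg1", "B", "kale", 1)
  rep_ <- classification_report(between, within, cat_)
  expect_equal(rep_$constitutive$A$over, "d1")
  expect_length(rep_$constitutive$B$over, 0)
  expect_equal(rep_$shared$machinery, "d2")
  expect_equal(rep_$plastic_genes, "d2")
})
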