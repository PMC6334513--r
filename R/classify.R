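#' Constitutively unique genes per species
#'
#' A gene is constitutively overexpressed in species S when, on the common
#' host, it is significantly higher in S than in EACH other species
#' (|log2FC| >= `lfc_threshold`, padj <= `padj_threshold`, consistent
#' direction in all pairwise contrasts); analogously for underexpression.
#' By construction a gene can be unique to at most one species per direction.
#'
#' @param de_between result of [de_between_species()] covering all unordered
#'   species pairs.
#' @param lfc_threshold log2 fold-change threshold (default 1).
#' @param padj_threshold adjusted-p threshold (default 0.05).
#' @return named list per species, each `list(over = ..., under = ...)` of
#'   gene id vectors.
#' @export
constitutive_unique <- function(de_between, lfc_threshold = 1,
                                padj_threshold = 0.05) {
  sp <- sort(unique(c(de_between$species_a, de_between$species_b)))
  empty <- lapply(sp, function(s) list(over = character(0), under = character(0)))
  names(empty) <- sp
  if (nrow(de_between) == 0L) return(empty)
  have <- unique(paste(de_between$species_a, de_between$species_b))
  want <- apply(t(combn(sp, 2L)), 1L, paste, collapse = " ")
  miss <- setdiff(want, have)
  if (length(miss))
    ds_stop("classify", "missing between-species contrast(s): ",
            paste(miss, collapse = "; "))
  genes <- unique(de_between$gene_id)
  res <- empty
  # up[g, s]: TRUE iff g significantly higher in s than the partner, per pair
  for (s in sp) {
    others <- setdiff(sp, s)
    over_all <- rep(TRUE, length(genes)); under_all <- rep(TRUE, length(genes))
    names(over_all) <- names(under_all) <- genes
    for (o in others) {
      sub <- de_between[(de_between$species_a == s & de_between$species_b == o) |
                        (de_between$species_a == o & de_between$species_b == s), ]
      # orient the fold change as s relative to o
      lfc <- ifelse(sub$species_b == s, sub$log2fc, -sub$log2fc)
      sig <- abs(lfc) >= lfc_threshold & sub$padj <= padj_threshold
      up <- setNames(sig & lfc > 0, sub$gene_id)
      dn <- setNames(sig & lfc < 0, sub$gene_id)
      over_all <- over_all & up[genes]
      under_all <- under_all & dn[genes]
    }
    res[[s]] <- list(over = genes[which(over_all)],
                     under = genes[which(under_all)])
  }
  res
}

#' Plastic response sets per species and plant, with pattern classes
#'
#' For every species and noncommon plant, the genes significantly regulated
#' after the transfer from the common host (threshold 0.58 log2, i.e. a
#' 1.5-fold change). Species are then classified by the number of plants on
#' which they show a large response: (a) "multi-host-high" if at least
#' `high_cut` called genes on >= 2 plants, (b) "single-host-high" if on
#' exactly one plant, (c) "low" otherwise.
#'
#' @param de_within result of [de_within_species()].
#' @param lfc_threshold log2 fold-change threshold (default 0.58).
#' @param padj_threshold adjusted-p threshold (default 0.05).
#' @param high_cut gene count defining a "high" per-plant response.
#' @param genes optional gene universe to restrict to (e.g. the catalog).
#' @return list with `sets` (per species, per plant: list(up, down)) and
#'   `pattern` (named character vector per species).
#' @export
plastic_sets <- function(de_within, lfc_threshold = 0.58,
                         padj_threshold = 0.05, high_cut = 20,
                         genes = NULL) {
  sp <- sort(unique(de_within$species))
  plants <- sort(unique(de_within$plant))
  if (!is.null(genes)) de_within <- de_within[de_within$gene_id %in% genes, ]
  sets <- list(); pattern <- setNames(character(length(sp)), sp)
  for (s in sp) {
    per_plant <- list()
    for (p in plants) {
      sub <- de_within[de_within$species == s & de_within$plant == p, ]
      if (nrow(sub) == 0L)
        ds_stop("classify", sprintf("missing contrast %s on %s", s, p))
      called <- call_de(sub, lfc_threshold, padj_threshold)
      per_plant[[p]] <- list(up = called$gene_id[called$call == "up"],
                             down = called$gene_id[called$call == "down"])
    }
    sets[[s]] <- per_plant
    nhigh <- sum(vapply(per_plant, function(x)
      length(x$up) + length(x$down), numeric(1)) >= high_cut)
    pattern[s] <- if (nhigh >= 2) "multi-host-high"
                  else if (nhigh == 1) "single-host-high" else "low"
  }
  list(sets = sets, pattern = pattern)
}

# internal: long table (gene, species, plant, direction) from plastic sets
plastic_calls_table <- function(psets) {
  rows <- list()
  for (s in names(psets$sets)) for (p in names(psets$sets[[s]])) {
    x <- psets$sets[[s]][[p]]
    if (length(x$up)) rows[[length(rows) + 1L]] <-
      data.frame(gene_id = x$up, species = s, plant = p, direction = "up",
                 stringsAsFactors = FALSE)
    if (length(x$down)) rows[[length(rows) + 1L]] <-
      data.frame(gene_id = x$down, species = s, plant = p, direction = "down",
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(0), species = character(0),
                      plant = character(0), direction = character(0)))
  do.call(rbind, rows)
}

#' Shared plastic genes and the essential detoxification machinery
#'
#' `shared_multi` is the set of genes plastically regulated (on any plant) in
#' more than one species. The `machinery` subset keeps only genes for which
#' at least two species share the same direction of regulation, i.e. a
#' consistent shared response.
#'
#' @param psets result of [plastic_sets()].
#' @return list with `shared_multi`, `machinery` (sorted gene id vectors) and
#'   `per_gene` (data.frame of species/direction calls).
#' @export
shared_machinery <- function(psets) {
  tab <- plastic_calls_table(psets)
  per_gene <- unique(tab[, c("gene_id", "species", "direction")])
  nsp <- tapply(per_gene$species, per_gene$gene_id,
                function(x) length(unique(x)))
  shared_multi <- sort(names(nsp)[nsp >= 2])
  consistent <- vapply(shared_multi, function(g) {
    sub <- per_gene[per_gene$gene_id == g, ]
    any(vapply(c("up", "down"), function(d)
      length(unique(sub$species[sub$direction == d])) >= 2, logical(1)))
  }, logical(1))
  list(shared_multi = shared_multi,
       machinery = shared_multi[consistent],
       per_gene = per_gene)
}

#' Family-enrichment chi-squared test against the catalog baseline
#'
#' Six-category goodness-of-fit of a gene set's family composition against
#' the family proportions of the full catalog (df = 5).
#'
#' @param gene_set character vector of gene ids, all present in the catalog.
#' @param catalog a [gene_catalog()].
#' @return list with `chi_square`, `df`, `p`, `observed`, `expected`.
#' @export
family_enrichment <- function(gene_set, catalog) {
  stopifnot(length(gene_set) >= 1L)
  missing <- setdiff(gene_set, catalog$gene_id)
  if (length(missing))
    ds_stop("classify", "genes not in catalog: ",
            paste(head(missing, 5L), collapse = ", "))
  fam <- catalog$family[match(gene_set, catalog$gene_id)]
  obs <- as.vector(table(factor(fam, levels = DETOX_FAMILIES)))
  props <- family_counts(catalog) / nrow(catalog)
  expd <- props * length(gene_set)
  chi <- sum((obs - expd)^2 / expd)
  df <- length(DETOX_FAMILIES) - 1L
  list(chi_square = chi, df = df, p = pchisq(chi, df, lower.tail = FALSE),
       observed = setNames(obs, DETOX_FAMILIES), expected = expd)
}

#' Full classification report for detoxification genes
#'
#' Applies the constitutive-unique, plastic and shared-machinery rules to DE
#' results restricted to the catalog universe, and runs the family-enrichment
#' tests on the shared lists.
#'
#' @param de_between result of [de_between_species()].
#' @param de_within result of [de_within_species()].
#' @param catalog a [gene_catalog()].
#' @param lfc_constitutive,lfc_plastic fold-change thresholds (1 and 0.58).
#' @param padj_threshold adjusted-p threshold (0.05).
#' @param high_cut per-plant gene count defining a "high" plastic response.
#' @return list: `constitutive`, `plastic`, `shared`, `enrichment_shared`,
#'   `enrichment_machinery`, `n_plastic_genes`.
#' @export
classification_report <- function(de_between, de_within, catalog,
                                  lfc_constitutive = 1, lfc_plastic = 0.58,
                                  padj_threshold = 0.05, high_cut = 20) {
  ids <- catalog$gene_id
  const <- constitutive_unique(
    de_between[de_between$gene_id %in% ids, , drop = FALSE],
    lfc_constitutive, padj_threshold)
  psets <- plastic_sets(de_within, lfc_plastic, padj_threshold, high_cut,
                        genes = ids)
  shared <- shared_machinery(psets)
  plastic_genes <- sort(unique(plastic_calls_table(psets)$gene_id))
  single <- setdiff(plastic_genes, shared$shared_multi)
  enr_shared <- if (length(shared$shared_multi))
    family_enrichment(shared$shared_multi, catalog) else NULL
  enr_mach <- if (length(shared$machinery))
    family_enrichment(shared$machinery, catalog) else NULL
  list(constitutive = const, plastic = psets, shared = shared,
       plastic_genes = plastic_genes, plastic_single = single,
       enrichment_shared = enr_shared, enrichment_machinery = enr_mach,
       n_plastic_genes = length(plastic_genes))
}
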