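#' Construct a detoxification gene catalog
#'
#' The catalog is the closed analysis universe: every classified gene must
#' belong to one of the six recognized detox families. Family proportions of
#' the full catalog are the expected baseline for enrichment tests.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param family character vector, each element one of [DETOX_FAMILIES].
#' @return a `gene_catalog`: data.frame with columns `gene_id`, `family`.
#' @export
gene_catalog <- function(gene_id, family) {
  gene_id <- as.character(gene_id)
  family <- as.character(family)
  if (length(gene_id) != length(family))
    ds_stop("catalog", "gene_id and family lengths differ")
  if (length(gene_id) == 0L)
    ds_stop("catalog", "empty catalog")
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup))
    ds_stop("catalog", "duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(family), DETOX_FAMILIES)
  if (length(bad)) {
    row <- which(family %in% bad)[1L]
    ds_stop("catalog", sprintf("unknown family '%s' (row %d, gene '%s')",
                               family[row], row, gene_id[row]))
  }
  out <- data.frame(gene_id = gene_id, family = family,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_catalog", "data.frame")
  out
}

#' Per-family gene counts of a catalog
#'
#' @param catalog a [gene_catalog()].
#' @return named integer vector over the six families; sums to catalog size.
#' @export
family_counts <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  tab <- table(factor(catalog$family, levels = DETOX_FAMILIES))
  out <- as.integer(tab)
  names(out) <- DETOX_FAMILIES
  out
}

#' Read a gene catalog from TSV
#'
#' Expects a tab-separated file with header columns `gene_id` and `family`.
#'
#' @param path file path.
#' @return a [gene_catalog()].
#' @export
read_gene_catalog <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) ds_stop("catalog", "empty catalog file: ", path)
  need <- c("gene_id", "family")
  if (!all(need %in% names(df)))
    ds_stop("catalog", "missing columns: ",
            paste(setdiff(need, names(df)), collapse = ", "))
  gene_catalog(df$gene_id, df$family)
}

#' Write a gene catalog to TSV
#' @param catalog a [gene_catalog()].
#' @param path output file path.
#' @export
write_gene_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  write.table(as.data.frame(catalog), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a sample design table
#'
#' One row per RNA sample of the species-by-plant factorial.
#'
#' @param sample_id unique sample identifiers.
#' @param species insect species label per sample.
#' @param plant host plant per sample; must come from [HOST_PLANTS].
#' @param replicate positive integer replicate index within a cell.
#' @return a `sample_design` data.frame.
#' @export
sample_design <- function(sample_id, species, plant, replicate) {
  sample_id <- as.character(sample_id)
  species <- as.character(species)
  plant <- as.character(plant)
  replicate <- as.integer(replicate)
  n <- length(sample_id)
  if (!all(lengths(list(species, plant, replicate)) == n))
    ds_stop("design", "column lengths differ")
  if (anyDuplicated(sample_id))
    ds_stop("design", "duplicate sample_id: ",
            paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  bad <- setdiff(unique(plant), HOST_PLANTS)
  if (length(bad))
    ds_stop("design", "unknown plant(s): ", paste(bad, collapse = ", "))
  if (any(is.na(replicate)) || any(replicate < 1L))
    ds_stop("design", "replicate must be a positive integer")
  out <- data.frame(sample_id = sample_id, species = species, plant = plant,
                    replicate = replicate, stringsAsFactors = FALSE)
  class(out) <- c("sample_design", "data.frame")
  out
}

#' The default 6-species x 4-plant x 3-replicate design
#'
#' Mirrors the study system: six cryptic whitefly species, four host plants,
#' three feeding replicates each (72 samples).
#'
#' @param species character vector of species names.
#' @param n_rep replicates per cell.
#' @return a [sample_design()].
#' @export
default_design <- function(species = default_species(), n_rep = 3L) {
  grid <- expand.grid(replicate = seq_len(n_rep), plant = HOST_PLANTS,
                      species = species, stringsAsFactors = FALSE)
  sample_design(
    sample_id = sprintf("%s_%s_r%d", grid$species, grid$plant, grid$replicate),
    species = grid$species, plant = grid$plant, replicate = grid$replicate)
}

#' Species names of the default scenario
#'
#' The six cryptic species analysed, spanning the high-performance
#' (MEAM1, AsiaII-1, SSA1-SG3) and low-performance (NW2, MED-Q1, Uganda-ASL)
#' host-use groups.
#' @return character vector of length 6.
#' @export
default_species <- function() {
  c("MEAM1", "AsiaII-1", "SSA1-SG3", "NW2", "MED-Q1", "Uganda-ASL")
}

#' The empirical host-performance grouping of the default species
#' @return a [performance_grouping()].
#' @export
default_grouping <- function() {
  performance_grouping(high = c("MEAM1", "AsiaII-1", "SSA1-SG3"),
                       low = c("NW2", "MED-Q1", "Uganda-ASL"))
}

#' Construct a performance grouping
#'
#' Bipartition of the species set into "high" and "low" host-performance
#' groups.
#'
#' @param high,low disjoint non-empty character vectors whose union is the
#'   species set.
#' @return a `performance_grouping` list with elements `high`, `low`.
#' @export
performance_grouping <- function(high, low) {
  high <- as.character(high); low <- as.character(low)
  if (length(high) == 0L || length(low) == 0L)
    ds_stop("grouping", "both groups must be non-empty")
  if (length(intersect(high, low)))
    ds_stop("grouping", "groups overlap: ",
            paste(intersect(high, low), collapse = ", "))
  structure(list(high = high, low = low), class = "performance_grouping")
}

# internal: check a counts matrix is valid and aligned with a design
validate_counts <- function(counts, design, stage = "counts") {
  if (!is.matrix(counts)) ds_stop(stage, "counts must be a matrix")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    ds_stop(stage, "gene ids (rownames) must be present and unique")
  if (any(is.na(counts))) ds_stop(stage, "NA entries in counts")
  if (any(counts < 0)) ds_stop(stage, "negative entries in counts")
  if (any(counts != floor(counts))) ds_stop(stage, "non-integer entries in counts")
  if (!identical(colnames(counts), design$sample_id)) {
    extra <- setdiff(colnames(counts), design$sample_id)
    miss <- setdiff(design$sample_id, colnames(counts))
    if (length(extra) || length(miss))
      ds_stop(stage, "sample mismatch; in counts only: [",
              paste(extra, collapse = ", "), "]; in design only: [",
              paste(miss, collapse = ", "), "]")
    counts <- counts[, design$sample_id, drop = FALSE]
  }
  counts
}

#' Read a gene x sample count matrix with its sample design
#'
#' Counts are TSV, genes as rows (first column `gene_id`), one column per
#' sample. The design is CSV with columns `sample_id`, `species`, `plant`,
#' `replicate`. Sample order is normalized to design order.
#'
#' @param path counts TSV path.
#' @param design_path design CSV path.
#' @return list with elements `counts` (integer matrix) and `design`.
#' @export
read_count_matrix <- function(path, design_path) {
  design <- read_sample_design(design_path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df))
    ds_stop("counts", "first column must be gene_id")
  genes <- as.character(df$gene_id)
  mat <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  if (!is.numeric(mat)) ds_stop("counts", "non-numeric entries in counts")
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  mat <- validate_counts(mat, design)
  storage.mode(mat) <- "integer"
  list(counts = mat, design = design)
}

#' Write a count matrix to TSV
#' @param counts gene x sample integer matrix with dimnames.
#' @param path output TSV path.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design CSV
#' @param path CSV with columns sample_id, species, plant, replicate.
#' @return a [sample_design()].
#' @export
read_sample_design <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "plant", "replicate")
  if (!all(need %in% names(df)))
    ds_stop("design", "missing columns: ",
            paste(setdiff(need, names(df)), collapse = ", "))
  sample_design(df$sample_id, df$species, df$plant, df$replicate)
}

#' Write a sample design CSV
#' @param design a [sample_design()].
#' @param path output CSV path.
#' @export
write_sample_design <- function(design, path) {
  write.csv(as.data.frame(design), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a newick file
#'
#' Thin wrapper over [ape::read.tree()] that validates branch lengths and
#' rootedness. Multifurcating or unrooted trees are accepted but flagged in
#' the log, since downstream reconstruction handles multifurcations natively.
#'
#' @param path newick file path.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) ds_stop("tree", "could not parse newick: ", path)
  if (is.null(tree$edge.length))
    ds_stop("tree", "tree has no branch lengths")
  if (any(is.na(tree$edge.length)) || any(tree$edge.length < 0))
    ds_stop("tree", "missing or negative branch length")
  if (anyDuplicated(tree$tip.label))
    ds_stop("tree", "duplicate tip labels")
  if (!ape::is.rooted(tree)) ds_log("tree %s is unrooted", path)
  if (!ape::is.binary(tree)) ds_log("tree %s contains multifurcations", path)
  tree
}

#' Read a binary host presence/absence matrix from CSV
#'
#' Rows are species groups, columns host taxa; entries must be 0/1.
#'
#' @param path CSV path; first column holds row labels.
#' @param level taxon level tag recorded on the result
#'   (one of "order", "family", "genus").
#' @return 0/1 matrix with attribute `level`.
#' @export
read_host_matrix <- function(path, level = "order") {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  mat <- as.matrix(df)
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat)))
    ds_stop("hosts", "duplicate row or column labels")
  if (any(is.na(mat)) || !all(mat %in% c(0, 1)))
    ds_stop("hosts", "entries must be 0/1")
  storage.mode(mat) <- "integer"
  attr(mat, "level") <- match.arg(level, c("order", "family", "genus"))
  mat
}

#' Write a host matrix to CSV
#' @param mat binary matrix with dimnames.
#' @param path output CSV path.
#' @export
write_host_matrix <- function(mat, path) {
  df <- data.frame(group = rownames(mat), mat, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a survival table from CSV
#'
#' Columns: species, plant, replicate, proportion_survived (in [0, 1]).
#'
#' @param path CSV path.
#' @return a `survival_table` data.frame.
#' @export
read_survival <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "plant", "replicate", "proportion_survived")
  if (!all(need %in% names(df)))
    ds_stop("survival", "missing columns: ",
            paste(setdiff(need, names(df)), collapse = ", "))
  survival_table(df$species, df$plant, df$replicate, df$proportion_survived)
}

#' Construct a survival table
#' @param species,plant,replicate assay factors.
#' @param proportion_survived proportion of adults alive after feeding,
#'   in the closed unit interval.
#' @return a `survival_table` data.frame.
#' @export
survival_table <- function(species, plant, replicate, proportion_survived) {
  p <- as.numeric(proportion_survived)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    ds_stop("survival", "proportions must lie in [0, 1]")
  out <- data.frame(species = as.character(species),
                    plant = as.character(plant),
                    replicate = as.integer(replicate),
                    proportion_survived = p, stringsAsFactors = FALSE)
  class(out) <- c("survival_table", "data.frame")
  out
}

#' Write a survival table to CSV
#' @param tab a [survival_table()].
#' @param path output CSV path.
#' @export
write_survival <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
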