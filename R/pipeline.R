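#' Default pipeline configuration
#'
#' Flat list of input paths, thresholds and options understood by
#' [run_pipeline()]. Any subset can be overridden in a YAML config file.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "detoxshift_out",
    stages = c("simulate", "de", "classify", "clusternull", "performance"),
    counts = NULL, design = NULL, catalog = NULL,
    tree = NULL, hosts = NULL, survival = NULL,
    host_level = "order",
    n_background = 25000,
    min_reads = 10, sample_fraction = 0.04,
    lfc_constitutive = 1, lfc_plastic = 0.58, padj = 0.05, high_cut = 20,
    survey_linkage = "complete", survey_cut = 4, survey_min_fraction = 0.5,
    null_subset = 266, null_trials = 500, null_pool = "background",
    grouping_high = default_grouping()$high,
    grouping_low = default_grouping()$low,
    alpha = 0.05)
}

# internal: merge a user config (list or YAML path) over the defaults
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) ds_stop("config", "config must be a list or YAML path")
  cfg <- default_config()
  cfg[names(config)] <- config
  cfg
}

# internal: append to the run log (no timestamps: outputs must be
# byte-identical across reruns with the same config and seed)
pipeline_log <- function(state, fmt, ...) {
  line <- sprintf(fmt, ...)
  cat(line, "\n", file = state$logfile, sep = "", append = TRUE)
  ds_log("%s", line)
}

#' Run the analysis pipeline
#'
#' Chains the requested stages, writing per-stage TSV/JSON outputs plus a
#' `run.log` recording versions, seed, thresholds and post-filter
#' dimensions. Rerunning with the same config and seed reproduces every
#' output byte-identically.
#'
#' Stages: `simulate` (synthetic counts/design/catalog/truth),
#' `survey` (host-range clustering), `ancestral` (host-state
#' reconstruction), `de` (filter/normalize/test), `classify`
#' (constitutive/plastic/machinery report), `clusternull` (random-subset
#' permutation test), `performance` (survival statistics).
#'
#' @param config list or YAML file path; see [default_config()].
#' @return invisibly, a named list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env()
  state$logfile <- file.path(cfg$outdir, "run.log")
  cat("", file = state$logfile)
  pipeline_log(state, "detoxshift %s | R %s.%s | seed %s",
               as.character(utils::packageVersion("detoxshift")),
               R.version$major, R.version$minor, cfg$seed)
  pipeline_log(state,
    "thresholds: lfc_constitutive=%g lfc_plastic=%g padj=%g min_reads=%g sample_fraction=%g",
    cfg$lfc_constitutive, cfg$lfc_plastic, cfg$padj, cfg$min_reads,
    cfg$sample_fraction)
  res <- list()
  grouping <- performance_grouping(cfg$grouping_high, cfg$grouping_low)

  for (stage in cfg$stages) {
    switch(stage,
      simulate = {
        sim <- simulate_counts(default_design(),
                               default_scenario(n_background = cfg$n_background),
                               seed = cfg$seed)
        write_count_matrix(sim$counts, file.path(cfg$outdir, "counts.tsv"))
        write_sample_design(sim$design, file.path(cfg$outdir, "design.csv"))
        write_gene_catalog(sim$catalog, file.path(cfg$outdir, "catalog.tsv"))
        jsonlite::write_json(sim$truth$genes,
                             file.path(cfg$outdir, "truth.json"),
                             dataframe = "rows", digits = NA)
        pipeline_log(state, "simulate: %d genes x %d samples",
                     nrow(sim$counts), ncol(sim$counts))
        res$simulate <- sim
      },
      survey = {
        if (is.null(cfg$hosts))
          ds_stop("survey", "config requests survey but no hosts path")
        hosts <- read_host_matrix(cfg$hosts, cfg$host_level)
        d <- binary_euclidean_distance(hosts)
        dend <- hierarchical_cluster(d, cfg$survey_linkage)
        clusters <- cut_into_k(dend, cfg$survey_cut)
        taxa <- shared_taxa(hosts, cfg$survey_min_fraction)
        write.table(data.frame(group = names(clusters), cluster = clusters),
                    file.path(cfg$outdir, "survey_clusters.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(dendrogram_newick(dend),
                   file.path(cfg$outdir, "survey_dendrogram.nwk"))
        jsonlite::write_json(list(shared_taxa = taxa),
                             file.path(cfg$outdir, "survey_shared.json"))
        pipeline_log(state, "survey: %d groups -> %d clusters, %d shared taxa",
                     nrow(hosts), cfg$survey_cut, length(taxa))
        res$survey <- list(dendrogram = dend, clusters = clusters,
                           shared = taxa)
      },
      ancestral = {
        if (is.null(cfg$tree) || is.null(cfg$hosts))
          ds_stop("ancestral", "config requests ancestral but tree/hosts missing")
        tree <- read_newick(cfg$tree)
        hosts <- read_host_matrix(cfg$hosts, cfg$host_level)
        rep_ <- ancestral_host_report(tree, hosts)
        write.table(rep_, file.path(cfg$outdir, "ancestral.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        pipeline_log(state, "ancestral: %d characters on %d tips",
                     nrow(rep_), length(tree$tip.label))
        res$ancestral <- rep_
      },
      de = {
        if (!is.null(res$simulate)) {
          counts <- res$simulate$counts; design <- res$simulate$design
        } else {
          if (is.null(cfg$counts) || is.null(cfg$design))
            ds_stop("de", "config requests de but counts/design missing")
          cd <- read_count_matrix(cfg$counts, cfg$design)
          counts <- cd$counts; design <- cd$design
        }
        filtered <- filter_low_counts(counts, cfg$min_reads,
                                      cfg$sample_fraction)
        pipeline_log(state, "de: %d of %d genes retained by filter",
                     nrow(filtered), nrow(counts))
        sf <- size_factors_median_ratio(filtered)
        disp <- estimate_dispersion(filtered, sf, design)
        rld <- regularized_log(filtered, sf)
        between <- de_between_species(filtered, sf, disp, design)
        within <- de_within_species(filtered, sf, disp, design)
        write_count_matrix(filtered,
                           file.path(cfg$outdir, "counts_filtered.tsv"))
        write.table(format(rld, digits = 8),
                    file.path(cfg$outdir, "rld.tsv"),
                    sep = "\t", quote = FALSE, col.names = NA)
        write.table(between, file.path(cfg$outdir, "de_between.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(within, file.path(cfg$outdir, "de_within.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        res$de <- list(counts = filtered, design = design,
                       size_factors = sf, dispersions = disp, rld = rld,
                       between = between, within = within)
      },
      classify = {
        if (is.null(res$de)) ds_stop("classify", "classify requires the de stage")
        catalog <- if (!is.null(res$simulate)) res$simulate$catalog
                   else if (!is.null(cfg$catalog)) read_gene_catalog(cfg$catalog)
                   else ds_stop("classify", "no catalog available")
        rep_ <- classification_report(res$de$between, res$de$within, catalog,
                                      cfg$lfc_constitutive, cfg$lfc_plastic,
                                      cfg$padj, cfg$high_cut)
        out <- list(
          constitutive = rep_$constitutive,
          pattern = as.list(rep_$plastic$pattern),
          shared_multi = rep_$shared$shared_multi,
          machinery = rep_$shared$machinery,
          n_plastic_genes = rep_$n_plastic_genes,
          enrichment_shared = rep_$enrichment_shared[c("chi_square", "df", "p")],
          enrichment_machinery = rep_$enrichment_machinery[c("chi_square", "df", "p")])
        jsonlite::write_json(out, file.path(cfg$outdir, "classification.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
        pipeline_log(state,
          "classify: %d plastic genes, %d shared, %d machinery",
          rep_$n_plastic_genes, length(rep_$shared$shared_multi),
          length(rep_$shared$machinery))
        res$classify <- rep_
      },
      clusternull = {
        if (is.null(res$de)) ds_stop("clusternull", "clusternull requires the de stage")
        catalog_ids <- if (!is.null(res$simulate)) res$simulate$catalog$gene_id
                       else if (!is.null(cfg$catalog)) read_gene_catalog(cfg$catalog)$gene_id
                       else character(0)
        pool <- switch(cfg$null_pool,
          background = setdiff(rownames(res$de$rld), catalog_ids),
          catalog = intersect(rownames(res$de$rld), catalog_ids),
          all = rownames(res$de$rld),
          ds_stop("clusternull", "null_pool must be background/catalog/all"))
        nt <- random_subset_null(res$de$rld, res$de$design, grouping,
                                 subset_size = cfg$null_subset,
                                 n_trials = cfg$null_trials, seed = cfg$seed,
                                 pool = pool)
        jsonlite::write_json(unclass(nt),
                             file.path(cfg$outdir, "clusternull.json"),
                             auto_unbox = TRUE, digits = NA)
        pipeline_log(state, "clusternull: %d/%d successes (pool %s, %d genes)",
                     nt$n_success, nt$n_trials, cfg$null_pool, length(pool))
        res$clusternull <- nt
      },
      performance = {
        surv <- if (!is.null(cfg$survival)) read_survival(cfg$survival)
                else if ("simulate" %in% cfg$stages)
                  simulate_survival(default_survival_means(grouping),
                                    seed = cfg$seed)
                else ds_stop("performance", "no survival data available")
        anova_tab <- two_way_anova(surv)
        letters_ <- performance_letters(surv, cfg$alpha)
        out <- list(
          anova = cbind(effect = rownames(anova_tab), anova_tab),
          letters = lapply(letters_, function(x) as.list(x$letters)))
        jsonlite::write_json(out, file.path(cfg$outdir, "performance.json"),
                             auto_unbox = TRUE, digits = NA, dataframe = "rows")
        pipeline_log(state, "performance: species p=%.4g plant p=%.4g",
                     anova_tab["species", "p"], anova_tab["plant", "p"])
        res$performance <- list(survival = surv, anova = anova_tab,
                                letters = letters_)
      },
      ds_stop("pipeline", "unknown stage: ", stage))
  }
  invisible(res)
}
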