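#' Pipeline configuration
#'
#' Collects every input path and threshold of the end-to-end regulon
#' discovery run.
#'
#' @param genome Path to the genome FASTA.
#' @param genes Path to the gene annotation (GFF3 or BED6).
#' @param expr Path to the replicated FPKM TSV.
#' @param catalog Path to the gene-to-category TSV (optional; enrichment is
#'   skipped when `NULL`).
#' @param site_matrix Path to a 4-row frequency-matrix TSV, or a
#'   `frequency_matrix` object.
#' @param outdir Output directory.
#' @param promoter_length Upstream region scanned per gene (bp). Default
#'   1000.
#' @param stringency_threshold Site-calling stringency cutoff (strict `>`).
#'   Default 0.6.
#' @param fc_threshold Linear fold-change threshold. Default 3.
#' @param fpkm_floor Minimum expression floor in FPKM. Default 20.
#' @param alpha Enrichment significance level on the raw p value. Default
#'   `5e-5`.
#' @param cut_similarity Clustering tree-cut similarity. Default 0.7.
#' @param min_cluster_size Minimum cluster size. Default 3.
#' @param wt_strain,mutant_strain Strain labels in the expression design.
#' @param inducing_conditions Conditions in which the factor acts. Default
#'   `c("rha", "pectin")`.
#' @param reference_condition No-carbon reference condition for the Venn
#'   binning. Default `"NoC"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, genes, expr, catalog = NULL,
                            site_matrix, outdir,
                            promoter_length = 1000,
                            stringency_threshold = 0.6,
                            fc_threshold = 3, fpkm_floor = 20,
                            alpha = 5e-5, cut_similarity = 0.7,
                            min_cluster_size = 3,
                            wt_strain = "WT", mutant_strain = "mutant",
                            inducing_conditions = c("rha", "pectin"),
                            reference_condition = "NoC") {
  if (fpkm_floor < 0) contract_error("fpkm_floor must be >= 0")
  if (alpha <= 0 || alpha > 1) contract_error("alpha must be in (0, 1]")
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(name, fun) {
  tryCatch(fun(), error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
          class = "regulonscan_stage_error", parent = e)
  })
}

#' Run the full regulon-discovery pipeline
#'
#' Executes the five analysis stages — promoter scanning, fold-change
#' classification, hierarchical clustering, category enrichment, and the
#' core-regulon intersection — writing one result TSV per stage plus a
#' machine-readable `manifest.json` (thresholds, input checksums, stage
#' list) into the output directory. Reruns on identical inputs produce
#' byte-identical result tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the per-stage results (`sites`,
#'   `site_counts`, `effects`, `bins`, `clustering`, `cluster_labels`,
#'   `enrichment`, `regulon`, `report`) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)

  # -- scan ------------------------------------------------------------
  scan_res <- run_stage("scan", function() {
    genome <- read_genome(config$genome)
    ann <- read_annotation(config$genes)
    fm <- if (inherits(config$site_matrix, "frequency_matrix")) {
      config$site_matrix
    } else {
      frequency_matrix(read_matrix_tsv(config$site_matrix))
    }
    bg <- background_from_genome(genome)
    sm <- log_likelihood_transform(fm, bg)
    cfg <- scan_config(config$promoter_length, config$stringency_threshold)
    sites <- scan_genome(genome, ann, sm, cfg)
    write_sites_bed(sites, out("sites.bed"))
    counts <- site_counts(sites)
    readr::write_tsv(counts, out("site_counts.tsv"))
    list(sites = sites, counts = counts, scan_config = cfg)
  })

  # -- de --------------------------------------------------------------
  de_res <- run_stage("de", function() {
    expr <- read_expression(config$expr)
    effects <- purrr::map(config$inducing_conditions, function(cond) {
      regulator_effect_sets(expr, cond, config$wt_strain, config$mutant_strain,
                            fc_threshold = config$fc_threshold,
                            fpkm_floor = config$fpkm_floor)
    })
    names(effects) <- config$inducing_conditions
    recs <- purrr::imap(effects, function(e, cond) {
      dplyr::mutate(attr(e, "records"), condition = cond)
    })
    readr::write_tsv(dplyr::bind_rows(recs), out("contrasts.tsv"))
    up_sets <- list()
    for (strain in c(config$wt_strain, config$mutant_strain)) {
      for (cond in config$inducing_conditions) {
        rec <- classify_contrast(expr, strain, config$reference_condition,
                                 strain, cond,
                                 fc_threshold = config$fc_threshold,
                                 fpkm_floor = config$fpkm_floor)
        up_sets[[paste0(strain, ".", cond)]] <- rec$gene_id[rec$call == "up"]
      }
    }
    bins <- venn_decompose(up_sets)
    bins_flat <- dplyr::mutate(
      bins, genes = purrr::map_chr(.data$genes, paste, collapse = ","),
      sets = NULL)
    readr::write_tsv(bins_flat, out("bins.tsv"))
    list(expr = expr, effects = effects, bins = bins)
  })

  # -- cluster ---------------------------------------------------------
  cl_res <- run_stage("cluster", function() {
    affected <- do.call(select_affected_genes, unname(de_res$effects))
    if (length(affected) < 2) {
      contract_error("fewer than 2 factor-affected genes; nothing to cluster")
    }
    clustering <- cluster_expression(de_res$expr, affected,
                                     cut_similarity = config$cut_similarity,
                                     min_cluster_size = config$min_cluster_size)
    labels <- label_clusters(clustering)
    asg <- dplyr::left_join(clustering$assignments,
                            dplyr::select(labels, "cluster",
                                          label_strain = "strain",
                                          label_condition = "condition"),
                            by = "cluster")
    readr::write_tsv(asg, out("clusters.tsv"))
    if (!is.null(clustering$linkage)) {
      readr::write_tsv(clustering$linkage, out("linkage.tsv"))
    }
    list(clustering = clustering, labels = labels)
  })

  # -- enrich ----------------------------------------------------------
  en_res <- run_stage("enrich", function() {
    if (is.null(config$catalog)) return(list(enrichment = NULL))
    catalog <- propagate_annotations(read_catalog(config$catalog))
    universe <- intersect(unique(de_res$expr$gene_id), unique(catalog$gene_id))
    affected <- do.call(select_affected_genes, unname(de_res$effects))
    bins <- c(stats::setNames(de_res$bins$genes, de_res$bins$bin),
              list(factor_affected = affected))
    res <- purrr::imap(bins, function(g, nm) {
      r <- enrich_bin(g, catalog, universe, alpha = config$alpha)
      if (nrow(r) > 0) dplyr::mutate(r, bin = nm, .before = 1) else NULL
    })
    enrichment <- dplyr::bind_rows(res)
    readr::write_tsv(enrichment, out("enrichment.tsv"))
    list(enrichment = enrichment)
  })

  # -- regulon ---------------------------------------------------------
  reg_res <- run_stage("regulon", function() {
    orphan <- setdiff(scan_res$counts$gene_id, unique(de_res$expr$gene_id))
    if (length(orphan) > 0) {
      warn(paste0(length(orphan),
                  " motif-bearing gene(s) absent from the expression matrix excluded"))
    }
    selected <- affected_clusters(cl_res$labels, config$inducing_conditions)
    entries <- core_regulon(scan_res$counts, cl_res$clustering, selected)
    report <- regulon_report(entries, scan_res$scan_config,
                             cl_res$clustering$params)
    write_regulon_tsv(report, out("regulon.tsv"))
    list(entries = entries, report = report, selected = selected)
  })

  inputs <- c(genome = config$genome, genes = config$genes, expr = config$expr)
  if (!is.null(config$catalog)) inputs <- c(inputs, catalog = config$catalog)
  if (is.character(config$site_matrix)) {
    inputs <- c(inputs, site_matrix = config$site_matrix)
  }
  manifest <- list(
    package = "regulonscan",
    version = as.character(utils::packageVersion("regulonscan")),
    stages = c("scan", "de", "cluster", "enrich", "regulon"),
    thresholds = list(
      promoter_length = config$promoter_length,
      stringency_threshold = config$stringency_threshold,
      fc_threshold = config$fc_threshold,
      fpkm_floor = config$fpkm_floor,
      alpha = config$alpha,
      cut_similarity = config$cut_similarity,
      min_cluster_size = config$min_cluster_size
    ),
    inputs = as.list(unname(tools::md5sum(inputs))) |>
      stats::setNames(names(inputs))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    sites = scan_res$sites, site_counts = scan_res$counts,
    effects = de_res$effects, bins = de_res$bins,
    clustering = cl_res$clustering, cluster_labels = cl_res$labels,
    enrichment = en_res$enrichment,
    regulon = reg_res$entries, report = reg_res$report,
    selected_clusters = reg_res$selected,
    manifest = manifest
  ))
}
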