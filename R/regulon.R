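#' Intersect motif-bearing genes with factor-affected clusters
#'
#' The core regulon is the set of genes that both carry at least one
#' promoter binding site and fall in one of the selected expression
#' clusters.
#'
#' @param site_genes Tibble with columns `gene_id`, `n_sites` (from
#'   [site_counts()]); only genes with `n_sites >= 1` are considered.
#' @param clusters A `regulon_clustering` object (or its [tidy()]
#'   assignments tibble with columns `gene_id`, `cluster`).
#' @param selected_clusters Character vector of cluster labels to intersect
#'   with (for example from [affected_clusters()]).
#' @param annotations Optional tibble `gene_id`, `annotation` joined into
#'   the result.
#' @return Tibble sorted by `gene_id`: `gene_id`, `annotation`, `n_sites`,
#'   `cluster`.
#' @export
core_regulon <- function(site_genes, clusters, selected_clusters,
                         annotations = NULL) {
  asg <- if (inherits(clusters, "regulon_clustering")) clusters$assignments else clusters
  known <- unique(asg$cluster)
  unknown <- setdiff(selected_clusters, known)
  if (length(unknown) > 0) {
    contract_error(paste0("unknown cluster label in selection: ", unknown[1]))
  }
  sites <- site_genes[site_genes$n_sites >= 1, , drop = FALSE]
  out <- asg %>%
    dplyr::filter(.data$cluster %in% selected_clusters) %>%
    dplyr::inner_join(sites, by = "gene_id") %>%
    dplyr::arrange(.data$gene_id)
  if (!is.null(annotations)) {
    out <- dplyr::left_join(out, annotations, by = "gene_id")
  } else {
    out$annotation <- NA_character_
  }
  dplyr::select(out, "gene_id", "annotation", "n_sites", "cluster")
}

#' Structured summary report of a core-regulon table
#'
#' @param entries Core-regulon tibble from [core_regulon()].
#' @param scan_config The [scan_config()] used for site discovery (recorded
#'   as provenance).
#' @param cluster_params Clustering parameter list (recorded as provenance).
#' @return An object of class `regulon_report`: list with `entries`,
#'   `per_cluster` (tibble `cluster`, `n_genes`), `site_histogram` (tibble
#'   `n_sites`, `n_genes`), and `provenance`.
#' @export
regulon_report <- function(entries, scan_config = NULL, cluster_params = NULL) {
  per_cluster <- entries %>% dplyr::count(.data$cluster, name = "n_genes")
  histo <- entries %>% dplyr::count(.data$n_sites, name = "n_genes")
  structure(
    list(entries = entries, per_cluster = per_cluster,
         site_histogram = histo,
         provenance = list(scan = unclass(scan_config),
                           clustering = cluster_params,
                           n_entries = nrow(entries))),
    class = "regulon_report"
  )
}

#' @export
print.regulon_report <- function(x, ...) {
  cat("Core regulon:", nrow(x$entries), "genes\n")
  if (nrow(x$per_cluster) > 0) {
    cat("Genes per cluster:\n")
    print(as.data.frame(x$per_cluster), row.names = FALSE)
    cat("Promoter-site histogram:\n")
    print(as.data.frame(x$site_histogram), row.names = FALSE)
  }
  if (!is.null(x$provenance$scan)) {
    cat(sprintf("Thresholds: promoter %d bp, stringency > %g\n",
                x$provenance$scan$promoter_length,
                x$provenance$scan$stringency_threshold))
  }
  invisible(x)
}

#' Write a core-regulon table as TSV
#'
#' @param report A `regulon_report` (or a core-regulon entries tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regulon_tsv <- function(report, path) {
  entries <- if (inherits(report, "regulon_report")) report$entries else report
  readr::write_tsv(entries, path)
  invisible(path)
}
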