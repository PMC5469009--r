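#' Union of factor-affected gene sets across conditions
#'
#' Combines the repressed and activated sets of two (or more) per-condition
#' effect analyses into the subset used for hierarchical clustering.
#'
#' @param ... Effect tibbles from [regulator_effect_sets()] (or any tibbles
#'   with a `gene_id` column).
#' @return Sorted character vector of gene identifiers.
#' @export
select_affected_genes <- function(...) {
  sets <- list(...)
  sort(unique(unlist(purrr::map(sets, "gene_id"))))
}

profile_matrix <- function(expr, genes) {
  prof <- expr %>%
    dplyr::filter(.data$gene_id %in% genes) %>%
    dplyr::group_by(.data$gene_id, .data$strain, .data$condition) %>%
    dplyr::summarise(mean_fpkm = mean(.data$fpkm), .groups = "drop") %>%
    dplyr::mutate(cell = paste(.data$strain, .data$condition, sep = ".")) %>%
    dplyr::arrange(.data$cell)
  cols <- dplyr::distinct(prof, .data$cell, .data$strain, .data$condition)
  wide <- prof %>%
    dplyr::select("gene_id", "cell", "mean_fpkm") %>%
    tidyr::pivot_wider(names_from = "cell", values_from = "mean_fpkm") %>%
    dplyr::arrange(.data$gene_id)
  m <- as.matrix(wide[, cols$cell, drop = FALSE])
  rownames(m) <- wide$gene_id
  list(mat = m, columns = cols)
}

#' Hierarchically cluster factor-affected genes across condition profiles
#'
#' Replicate-averaged FPKM profiles are transformed `log2(FPKM + 1)` and
#' z-scored per gene, making the Pearson-correlation distance scale-free.
#' Agglomerative clustering (average linkage by default) is cut at a
#' correlation-similarity threshold; clusters smaller than
#' `min_cluster_size` become outliers, as do genes with zero profile
#' variance (their correlation to anything is undefined). Cluster labels
#' `C1, C2, ...` are assigned in decreasing size order, ties broken by the
#' lexicographically smallest member gene.
#'
#' @param expr Long expression tibble.
#' @param genes Character vector of gene identifiers to cluster (at least 2).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#'   Default `"average"`.
#' @param cut_similarity Correlation similarity at which the tree is cut;
#'   the tree height used is `1 - cut_similarity`. Default 0.7.
#' @param min_cluster_size Clusters smaller than this become outliers.
#'   Default 3.
#' @return An object of class `regulon_clustering`: list with
#'   `assignments` (tibble `gene_id`, `cluster`; outliers labeled
#'   `"outlier"`), `profiles` (z-scored matrix, genes by cells),
#'   `profile_columns` (tibble `cell`, `strain`, `condition`), `linkage`
#'   (merge-history tibble for reproducibility), `hclust`, and `params`.
#' @export
cluster_expression <- function(expr, genes, linkage = "average",
                               cut_similarity = 0.7, min_cluster_size = 3) {
  genes <- sort(unique(genes))
  if (length(genes) < 2) {
    if (length(genes) == 0) contract_error("no genes to cluster")
    pm <- profile_matrix(expr, genes)
    return(new_regulon_clustering(
      tibble(gene_id = genes, cluster = "outlier"),
      pm$mat * NA_real_, pm$columns, NULL,
      list(linkage = linkage, cut_similarity = cut_similarity,
           min_cluster_size = min_cluster_size)))
  }
  if (cut_similarity <= 0 || cut_similarity >= 1) {
    contract_error("cut_similarity must be in (0, 1)")
  }
  pm <- profile_matrix(expr, genes)
  if (ncol(pm$mat) < 2) contract_error("need at least 2 design cells to cluster")
  m <- log2(pm$mat + 1)
  sds <- apply(m, 1, stats::sd)
  flat <- sds == 0 | is.na(sds)
  if (any(flat)) {
    warn(paste0(sum(flat), " gene(s) with constant profiles assigned as outliers"))
  }
  z <- m
  z[!flat, ] <- t(scale(t(m[!flat, , drop = FALSE])))
  z[flat, ] <- NA_real_
  active <- rownames(m)[!flat]
  assignments <- tibble(gene_id = rownames(m),
                        cluster = rep("outlier", nrow(m)))
  hc <- NULL
  if (length(active) >= 2) {
    d <- stats::as.dist(1 - stats::cor(t(z[active, , drop = FALSE])))
    hc <- stats::hclust(d, method = linkage)
    raw <- stats::cutree(hc, h = 1 - cut_similarity)
    sizes <- table(raw)
    keep <- names(sizes)[sizes >= min_cluster_size]
    ord <- order(-sizes[keep],
                 vapply(keep, function(k) min(names(raw)[raw == k]), character(1)))
    relabel <- stats::setNames(paste0("C", seq_along(keep)), keep[ord])
    lab <- ifelse(as.character(raw) %in% keep,
                  relabel[as.character(raw)], "outlier")
    assignments$cluster[match(active, assignments$gene_id)] <- unname(lab)
  } else if (length(active) == 1 && min_cluster_size <= 1) {
    assignments$cluster[assignments$gene_id == active] <- "C1"
  }
  linkage_rec <- NULL
  if (!is.null(hc)) {
    linkage_rec <- tibble(
      step = seq_len(nrow(hc$merge)),
      left = hc$merge[, 1], right = hc$merge[, 2],
      height = hc$height
    )
  }
  new_regulon_clustering(assignments, z, pm$columns, hc,
                         list(linkage = linkage, cut_similarity = cut_similarity,
                              min_cluster_size = min_cluster_size),
                         linkage_rec)
}

new_regulon_clustering <- function(assignments, profiles, columns, hc, params,
                                   linkage_rec = NULL) {
  structure(
    list(assignments = assignments, profiles = profiles,
         profile_columns = columns, hclust = hc, linkage = linkage_rec,
         params = params),
    class = "regulon_clustering"
  )
}

#' @export
print.regulon_clustering <- function(x, ...) {
  g <- glance(x)
  cat("Hierarchical expression clustering:", g$n_genes, "genes in",
      g$n_clusters, "clusters with", g$n_outliers, "outliers\n")
  cat("  linkage:", x$params$linkage,
      " cut similarity:", x$params$cut_similarity,
      " min cluster size:", x$params$min_cluster_size, "\n")
  invisible(x)
}

#' Tidy the per-gene cluster assignments
#'
#' @param x A `regulon_clustering` object.
#' @param ... Unused.
#' @return Tibble with columns `gene_id`, `cluster`.
#' @method tidy regulon_clustering
#' @export
tidy.regulon_clustering <- function(x, ...) {
  x$assignments
}

#' One-row summary of a clustering
#'
#' @param x A `regulon_clustering` object.
#' @param ... Unused.
#' @return One-row tibble: `n_genes`, `n_clusters`, `n_outliers`,
#'   `cut_similarity`, `linkage`.
#' @method glance regulon_clustering
#' @export
glance.regulon_clustering <- function(x, ...) {
  cl <- x$assignments$cluster
  tibble(
    n_genes = length(cl),
    n_clusters = length(unique(cl[cl != "outlier"])),
    n_outliers = sum(cl == "outlier"),
    cut_similarity = x$params$cut_similarity,
    linkage = x$params$linkage
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Label clusters by their condition of maximal expression
#'
#' Each cluster is labeled with the strain/condition cell whose mean
#' z-scored expression over the cluster's genes is highest. Exact ties
#' resolve to the lexicographically first cell name and are flagged.
#'
#' @param result A `regulon_clustering` object.
#' @return Tibble with one row per cluster (outliers excluded): `cluster`,
#'   `strain`, `condition`, `mean_z`, `tie`.
#' @export
label_clusters <- function(result) {
  asg <- result$assignments
  clusters <- sort(unique(asg$cluster[asg$cluster != "outlier"]))
  cols <- result$profile_columns
  rows <- purrr::map(clusters, function(cl) {
    genes <- asg$gene_id[asg$cluster == cl]
    prof <- colMeans(result$profiles[genes, , drop = FALSE])
    best <- max(prof)
    hits <- which(prof == best)
    pick <- hits[order(cols$cell[hits])][1]
    tibble(cluster = cl, strain = cols$strain[pick],
           condition = cols$condition[pick], mean_z = best,
           tie = length(hits) > 1)
  })
  dplyr::bind_rows(rows)
}

#' Clusters whose label condition marks them as factor-affected
#'
#' The factor-affected clusters are those maximal in one of the inducing
#' conditions (in either strain) — the analog of selecting the
#' condition-specific clusters from a clustered heat map.
#'
#' @param labels Cluster-label tibble from [label_clusters()].
#' @param affected_conditions Conditions considered inducing. Default
#'   `c("rha", "pectin")`.
#' @return Character vector of cluster labels.
#' @export
affected_clusters <- function(labels, affected_conditions = c("rha", "pectin")) {
  labels$cluster[labels$condition %in% affected_conditions]
}
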