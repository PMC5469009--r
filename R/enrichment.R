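category_ancestors <- function(id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  vapply(seq_along(parts), function(i) paste(parts[seq_len(i)], collapse = "."),
         character(1))
}

#' Propagate gene annotations up the category hierarchy
#'
#' Dotted category identifiers encode their ancestry: a gene annotated to
#' `01.05.03` is implicitly annotated to `01.05` and `01` as well. This
#' closure makes category membership counts monotone along ancestor chains,
#' which enrichment at interior categories requires.
#'
#' @param catalog Tibble with columns `gene_id`, `category_id` (and
#'   optionally `label`), as from [read_catalog()].
#' @return The catalog with ancestor rows added and duplicates removed;
#'   ancestor categories inherit `NA` labels unless already present.
#' @export
propagate_annotations <- function(catalog) {
  if (nrow(catalog) == 0) return(catalog)
  check_category_ids(catalog$category_id)
  has_label <- "label" %in% names(catalog)
  expanded <- catalog %>%
    dplyr::mutate(.anc = purrr::map(.data$category_id, category_ancestors)) %>%
    tidyr::unnest(".anc") %>%
    dplyr::select(-"category_id") %>%
    dplyr::rename(category_id = ".anc") %>%
    dplyr::distinct(.data$gene_id, .data$category_id, .keep_all = TRUE)
  if (has_label) {
    # a propagated row must not borrow the leaf's label
    labels <- catalog %>%
      dplyr::filter(!is.na(.data$label)) %>%
      dplyr::distinct(.data$category_id, .data$label)
    expanded <- expanded %>%
      dplyr::select(-"label") %>%
      dplyr::left_join(labels, by = "category_id")
  }
  dplyr::arrange(expanded, .data$gene_id, .data$category_id)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` counts category members in a draw of `n` genes from
#' a universe of `N` genes of which `K` belong to the category — the
#' classical over-representation p value.
#'
#' @param k Observed overlap between the gene bin and the category.
#' @param n Bin size.
#' @param K Category size in the universe.
#' @param N Universe size.
#' @return A single probability in (0, 1].
#' @export
#' @examples
#' hypergeom_upper_tail(4, 5, 4, 10)  # C(4,4) * C(6,1) / C(10,5) = 6/252
hypergeom_upper_tail <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > n || n > N || K > N) {
    contract_error("hypergeometric arguments must satisfy 0 <= k <= n <= N and K <= N")
  }
  if (k > K) return(0)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Category over-representation in a gene bin
#'
#' Tests every category with at least one annotated gene in the universe for
#' over-representation in the bin with the one-sided hypergeometric upper
#' tail. Bins with `min_bin` or fewer genes are skipped (an empty result is
#' returned with attribute `skipped = TRUE`), mirroring the convention of
#' only reading enrichment off bins with more than 20 genes. No
#' multiple-testing correction is applied to the decision; a Bonferroni
#' column is reported for information.
#'
#' @param genes Character vector of bin gene identifiers.
#' @param catalog Propagated annotation catalog (see
#'   [propagate_annotations()]).
#' @param universe Character vector of universe gene identifiers. Bin genes
#'   outside the universe are dropped with a warning.
#' @param alpha Significance level on the raw p value. Default `5e-5`.
#' @param min_bin Bins must have strictly more than this many genes to be
#'   tested. Default 20.
#' @return Tibble sorted by p value: `category_id`, `label`, `k`, `n`, `K`,
#'   `N`, `p_value`, `bonferroni`, `significant`.
#' @export
enrich_bin <- function(genes, catalog, universe, alpha = 5e-5, min_bin = 20) {
  if (length(universe) == 0) contract_error("empty universe")
  empty <- tibble(category_id = character(), label = character(),
                  k = integer(), n = integer(), K = integer(), N = integer(),
                  p_value = numeric(), bonferroni = numeric(),
                  significant = logical())
  outside <- setdiff(genes, universe)
  if (length(outside) > 0) {
    warn(paste0(length(outside), " bin gene(s) outside the universe dropped"))
    genes <- intersect(genes, universe)
  }
  if (length(genes) <= min_bin) {
    attr(empty, "skipped") <- TRUE
    attr(empty, "reason") <- paste0("skipped: bin too small (", length(genes),
                                    " <= ", min_bin, ")")
    return(empty)
  }
  cat_u <- catalog[catalog$gene_id %in% universe, , drop = FALSE]
  if (nrow(cat_u) == 0) return(empty)
  has_label <- "label" %in% names(cat_u)
  Ktab <- cat_u %>%
    dplyr::distinct(.data$gene_id, .data$category_id) %>%
    dplyr::count(.data$category_id, name = "K")
  ktab <- cat_u %>%
    dplyr::filter(.data$gene_id %in% genes) %>%
    dplyr::distinct(.data$gene_id, .data$category_id) %>%
    dplyr::count(.data$category_id, name = "k")
  res <- Ktab %>%
    dplyr::left_join(ktab, by = "category_id") %>%
    dplyr::mutate(k = dplyr::coalesce(.data$k, 0L),
                  n = length(genes), N = length(universe))
  res$p_value <- purrr::pmap_dbl(
    list(res$k, res$n, res$K, res$N),
    function(k, n, K, N) hypergeom_upper_tail(k, n, K, N)
  )
  labels <- if (has_label) {
    cat_u %>%
      dplyr::filter(!is.na(.data$label)) %>%
      dplyr::distinct(.data$category_id, .data$label)
  } else {
    tibble(category_id = character(), label = character())
  }
  res %>%
    dplyr::left_join(labels, by = "category_id") %>%
    dplyr::mutate(
      bonferroni = pmin(1, .data$p_value * dplyr::n()),
      significant = .data$p_value <= alpha
    ) %>%
    dplyr::select("category_id", "label", "k", "n", "K", "N",
                  "p_value", "bonferroni", "significant") %>%
    dplyr::arrange(.data$p_value, .data$category_id)
}
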