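#' Replicate-averaged FPKM for one strain/condition cell
#'
#' @param expr Long expression tibble (see [read_expression()]).
#' @param strain,condition The design cell to average.
#' @return Tibble with columns `gene_id`, `mean_fpkm` (arithmetic mean across
#'   replicates).
#' @export
condition_means <- function(expr, strain, condition) {
  sub <- expr[expr$strain == strain & expr$condition == condition, , drop = FALSE]
  if (nrow(sub) == 0) {
    contract_error(paste0("no samples for strain '", strain,
                          "', condition '", condition, "'"))
  }
  sub %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(mean_fpkm = mean(.data$fpkm), .groups = "drop")
}

#' The log2 threshold corresponding to an x-fold change
#'
#' Returns `log2(fc_threshold)` rounded to two decimals, the form in which
#' fold-change cutoffs are conventionally quoted (a 3-fold change is the
#' log2 cutoff 1.58).
#'
#' @param fc_threshold Linear fold-change threshold (> 1).
#' @param digits Decimal places to round to. Default 2.
#' @return A single numeric.
#' @export
log2_fold_threshold <- function(fc_threshold, digits = 2) {
  if (fc_threshold <= 0) contract_error("fc_threshold must be positive")
  round(log2(fc_threshold), digits)
}

#' Classify genes by fold change between two design cells
#'
#' For each gene, replicate means are computed in both cells and the log2
#' fold change `log2((mean_b + epsilon) / (mean_a + epsilon))` is compared
#' against the threshold. Genes whose larger mean falls below `fpkm_floor`
#' are `filtered` and carry no call. With `printed_threshold = TRUE` the
#' comparison uses the two-decimal rounded log2 cutoff (1.58 for a 3-fold
#' threshold); by default the unrounded `log2(fc_threshold)` is used.
#'
#' @param expr Long expression tibble.
#' @param strain_a,cond_a Reference design cell (denominator).
#' @param strain_b,cond_b Test design cell (numerator).
#' @param fc_threshold Linear fold-change threshold. Default 3.
#' @param fpkm_floor Minimum expression: genes with
#'   `max(mean_a, mean_b) < fpkm_floor` are excluded from calling.
#'   Default 20 FPKM.
#' @param epsilon Small FPKM offset added to both means before the ratio to
#'   avoid division by zero. Default 0.1.
#' @param printed_threshold Use the rounded printed log2 cutoff instead of
#'   `log2(fc_threshold)` to machine precision. Default `FALSE`.
#' @return A tibble with one row per gene: `gene_id`, `mean_a`, `mean_b`,
#'   `log2fc`, `call` in `up` / `down` / `unchanged` / `filtered`.
#' @export
classify_contrast <- function(expr, strain_a, cond_a, strain_b, cond_b,
                              fc_threshold = 3, fpkm_floor = 20,
                              epsilon = 0.1, printed_threshold = FALSE) {
  if (fc_threshold <= 0) contract_error("fc_threshold must be positive")
  a <- condition_means(expr, strain_a, cond_a)
  b <- condition_means(expr, strain_b, cond_b)
  cutoff <- if (printed_threshold) log2_fold_threshold(fc_threshold) else log2(fc_threshold)
  rec <- dplyr::inner_join(
    dplyr::rename(a, mean_a = "mean_fpkm"),
    dplyr::rename(b, mean_b = "mean_fpkm"),
    by = "gene_id"
  )
  rec %>%
    dplyr::mutate(
      log2fc = log2((.data$mean_b + epsilon) / (.data$mean_a + epsilon)),
      call = dplyr::case_when(
        pmax(.data$mean_a, .data$mean_b) < fpkm_floor ~ "filtered",
        .data$log2fc >= cutoff ~ "up",
        .data$log2fc <= -cutoff ~ "down",
        TRUE ~ "unchanged"
      )
    ) %>%
    dplyr::arrange(.data$gene_id)
}

#' Summarize a fold-change contrast
#'
#' Tallies the calls of a [classify_contrast()] result: how many genes
#' passed the expression floor, how many changed in either direction, and
#' the percentage that did not change (rounded to whole percent, the form in
#' which genome-scale scatterplot summaries are quoted).
#'
#' @param records Tibble of per-gene records with a `call` column.
#' @return One-row tibble: `n_tested` (non-filtered genes), `n_up`, `n_down`,
#'   `n_changed`, `n_unchanged`, `pct_unchanged`.
#' @export
contrast_summary <- function(records) {
  tested <- records[records$call != "filtered", , drop = FALSE]
  n_up <- sum(tested$call == "up")
  n_down <- sum(tested$call == "down")
  tibble(
    n_tested = nrow(tested),
    n_up = n_up,
    n_down = n_down,
    n_changed = n_up + n_down,
    n_unchanged = nrow(tested) - n_up - n_down,
    pct_unchanged = round(100 * (nrow(tested) - n_up - n_down) / nrow(tested))
  )
}

#' Decompose named gene sets into disjoint Venn bins
#'
#' Every gene in the union of the input sets is assigned to exactly one bin
#' according to its exact membership signature, so the bins partition the
#' union (at most `2^n - 1` non-empty bins for `n` sets).
#'
#' @param sets Named list of 2–4 character vectors of gene identifiers.
#' @return A tibble with one row per non-empty bin: `bin` (signature label,
#'   set names joined by `&`), `sets` (list column of contributing set
#'   names), `genes` (list column of sorted gene identifiers), `n_genes`.
#' @export
venn_decompose <- function(sets) {
  if (length(sets) < 2) contract_error("venn_decompose needs at least 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    contract_error("all sets must be named")
  }
  if (anyDuplicated(names(sets))) contract_error("duplicate set names")
  universe <- sort(unique(unlist(sets)))
  if (length(universe) == 0) {
    return(tibble(bin = character(), sets = list(), genes = list(),
                  n_genes = integer()))
  }
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(sets)))
  sig <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  split_genes <- split(universe, sig)
  tibble(
    bin = names(split_genes),
    sets = purrr::map(names(split_genes), ~ strsplit(.x, "&", fixed = TRUE)[[1]]),
    genes = purrr::map(split_genes, sort),
    n_genes = lengths(split_genes)
  ) %>%
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$bin)
}

#' Genes repressed or activated by the transcription factor in one condition
#'
#' Contrasts the deletion mutant against the wild type within a single
#' condition. Genes up in the mutant are *repressed* by the factor (its loss
#' de-represses them); genes down in the mutant are *activated* by it. The
#' FPKM floor and fold-change rule are those of [classify_contrast()].
#'
#' @param expr Long expression tibble containing both strains.
#' @param condition Condition to contrast within.
#' @param wt_strain,mutant_strain Strain labels. Defaults `"WT"` and
#'   `"mutant"`.
#' @inheritParams classify_contrast
#' @return A tibble with columns `gene_id`, `effect` (`"repressed"` or
#'   `"activated"`); the full per-gene records are attached as attribute
#'   `records`.
#' @export
regulator_effect_sets <- function(expr, condition, wt_strain = "WT",
                                  mutant_strain = "mutant", fc_threshold = 3,
                                  fpkm_floor = 20, epsilon = 0.1,
                                  printed_threshold = FALSE) {
  for (s in c(wt_strain, mutant_strain)) {
    if (!any(expr$strain == s & expr$condition == condition)) {
      contract_error(paste0("strain '", s, "' not measured in condition '",
                            condition, "'"))
    }
  }
  rec <- classify_contrast(expr, wt_strain, condition, mutant_strain, condition,
                           fc_threshold = fc_threshold, fpkm_floor = fpkm_floor,
                           epsilon = epsilon, printed_threshold = printed_threshold)
  out <- rec %>%
    dplyr::filter(.data$call %in% c("up", "down")) %>%
    dplyr::mutate(effect = ifelse(.data$call == "up", "repressed", "activated")) %>%
    dplyr::select("gene_id", "effect")
  attr(out, "records") <- rec
  out
}
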