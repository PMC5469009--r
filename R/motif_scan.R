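BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, NULL), function(s) paste(rev(s), collapse = ""), character(1))
}

seq_to_idx <- function(x) {
  idx <- match(strsplit(x, NULL)[[1]], BASES)
  idx
}

#' Build a base-frequency matrix from aligned binding sites
#'
#' Counts each base at each motif position over a set of equal-length aligned
#' site sequences and converts counts to frequencies with an additive
#' pseudocount: `M[k, j] = (count[k, j] + pseudocount_total/4) /
#' (n_sites + pseudocount_total)`. A positive pseudocount guarantees strictly
#' positive frequencies, which the log-likelihood transform requires; motifs
#' assembled from a handful of sites otherwise contain zero counts.
#'
#' @param sites Character vector of equal-length DNA strings over
#'   `A, C, G, T`.
#' @param pseudocount_total Total pseudocount mass added per column, split
#'   equally across the four bases. Default 1.
#' @return An object of class `frequency_matrix`: a list with fields `mat`
#'   (4-by-L frequency matrix, rows `A, C, G, T`), `width`, `n_sites`,
#'   `pseudocount_total`.
#' @export
#' @examples
#' build_frequency_matrix(c("ACGT", "ACGA"), pseudocount_total = 1)
build_frequency_matrix <- function(sites, pseudocount_total = 1) {
  if (length(sites) < 1) contract_error("need at least one site sequence")
  if (pseudocount_total < 0) contract_error("pseudocount_total must be >= 0")
  L <- unique(nchar(sites))
  if (length(L) != 1) contract_error("site sequences have ragged lengths")
  if (L < 1) contract_error("site sequences are empty")
  if (any(stringr::str_detect(sites, "[^ACGT]"))) {
    contract_error("site sequences must be over the alphabet A, C, G, T")
  }
  chars <- matrix(unlist(strsplit(sites, NULL)), nrow = length(sites), byrow = TRUE)
  counts <- vapply(seq_len(L), function(j) {
    tabulate(match(chars[, j], BASES), nbins = 4)
  }, numeric(4))
  counts <- matrix(counts, nrow = 4, dimnames = list(BASES, NULL))
  M <- (counts + pseudocount_total / 4) / (length(sites) + pseudocount_total)
  structure(
    list(mat = M, width = L, n_sites = length(sites),
         pseudocount_total = pseudocount_total),
    class = "frequency_matrix"
  )
}

#' Wrap a numeric matrix as a frequency matrix
#'
#' @param mat A 4-by-L matrix of per-position base frequencies, rows named
#'   `A, C, G, T`; each column must sum to 1.
#' @return A `frequency_matrix` object.
#' @export
frequency_matrix <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == 4)
  if (is.null(rownames(mat))) rownames(mat) <- BASES
  mat <- mat[BASES, , drop = FALSE]
  if (any(abs(colSums(mat) - 1) > 1e-9)) {
    contract_error("frequency matrix columns must sum to 1")
  }
  structure(list(mat = mat, width = ncol(mat), n_sites = NA_integer_,
                 pseudocount_total = NA_real_),
            class = "frequency_matrix")
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat("Base-frequency matrix,", x$width, "positions\n")
  print(round(x$mat, 3))
  invisible(x)
}

#' Genome-wide background base frequencies
#'
#' Computes the frequency of each unambiguous base over all contigs.
#' `N` (and any other non-ACGT character) is excluded from both numerator
#' and denominator.
#'
#' @param genome Named character vector of contig sequences, as returned by
#'   [read_genome()].
#' @return Named numeric vector `b` of length 4 (`A, C, G, T`) summing to 1.
#' @export
background_from_genome <- function(genome) {
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(unname(genome)), letters = BASES))
  total <- sum(counts)
  if (total == 0) contract_error("genome contains no unambiguous A/C/G/T bases")
  stats::setNames(as.numeric(counts) / total, BASES)
}

#' Transform a frequency matrix to a normalized log-likelihood scoring matrix
#'
#' Each frequency is converted to a log2 likelihood ratio against the genomic
#' background: `P[k, j] = log2(M[k, j] / b[k])`. The object also carries the
#' maximum and minimum achievable window scores (column-wise sums of the best
#' and worst base), which define the stringency normalization.
#'
#' @param fm A `frequency_matrix` with strictly positive entries.
#' @param background Named numeric background frequencies over `A, C, G, T`,
#'   all strictly positive (see [background_from_genome()]).
#' @return An object of class `scoring_matrix`: list with fields `mat`
#'   (4-by-L log2-ratio matrix), `width`, `max_score`, `min_score`,
#'   `background`.
#' @export
log_likelihood_transform <- function(fm, background) {
  stopifnot(inherits(fm, "frequency_matrix"))
  b <- background[BASES]
  if (anyNA(b) || any(b <= 0)) {
    abort("all four background frequencies must be > 0",
          class = "regulonscan_background_error")
  }
  if (any(fm$mat <= 0)) {
    contract_error("frequency matrix has non-positive entries; use a positive pseudocount")
  }
  P <- log2(sweep(fm$mat, 1, b, "/"))
  # accumulate in the same order as window scoring so the argmax window's
  # score is bit-identical to max_score
  max_score <- 0
  min_score <- 0
  for (j in seq_len(ncol(P))) {
    max_score <- max_score + max(P[, j])
    min_score <- min_score + min(P[, j])
  }
  if (max_score <= 0) {
    abort("uninformative matrix: maximum achievable score is not positive, stringency is undefined",
          class = "regulonscan_uninformative_matrix")
  }
  structure(
    list(mat = P, width = ncol(P), max_score = max_score,
         min_score = min_score, background = b),
    class = "scoring_matrix"
  )
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("Log-likelihood scoring matrix,", x$width, "positions\n")
  cat("max score", round(x$max_score, 3), "bits; min score",
      round(x$min_score, 3), "bits\n")
  cat("consensus:", argmax_sequence(x), "\n")
  invisible(x)
}

#' Highest-scoring sequence of a scoring matrix
#'
#' Ties within a column resolve to the first base in `A, C, G, T` order.
#'
#' @param sm A `scoring_matrix`.
#' @return A single DNA string of length `sm$width` scoring `sm$max_score`.
#' @export
argmax_sequence <- function(sm) {
  paste(BASES[apply(sm$mat, 2, which.max)], collapse = "")
}

#' Scan configuration
#'
#' @param promoter_length Length in bp of the upstream region scanned per
#'   gene. Default 1000.
#' @param stringency_threshold Sites are reported when their stringency is
#'   strictly greater than this value. Default 0.6.
#' @param both_strands Scan the reverse complement as well. Default `TRUE`.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(promoter_length = 1000, stringency_threshold = 0.6,
                        both_strands = TRUE) {
  if (promoter_length < 1) contract_error("promoter_length must be >= 1")
  if (stringency_threshold <= 0 || stringency_threshold > 1) {
    contract_error("stringency_threshold must be in (0, 1]")
  }
  structure(list(promoter_length = as.integer(promoter_length),
                 stringency_threshold = stringency_threshold,
                 both_strands = isTRUE(both_strands)),
            class = "scan_config")
}

#' Extract strand-aware upstream promoter regions
#'
#' For a `+` gene the promoter is the interval `[gene_start - Lp,
#' gene_start)`; for a `-` gene it is `[gene_end, gene_end + Lp)`, and the
#' returned sequence is reverse-complemented so that it always reads in
#' promoter-forward orientation (position 0 is the far upstream end).
#' Promoters are truncated at contig boundaries.
#'
#' @param genome Named character vector of contig sequences.
#' @param annotation Gene-model tibble from [read_annotation()].
#' @param promoter_length Upstream length in bp (default 1000).
#' @return A tibble with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `sequence` — `start`/`end` are the genomic promoter interval
#'   (0-based half-open); `strand` is the gene's strand.
#' @export
extract_promoters <- function(genome, annotation, promoter_length = 1000) {
  missing <- setdiff(annotation$contig, names(genome))
  if (length(missing) > 0) {
    contract_error(paste0("gene on unknown contig: ", missing[1]))
  }
  clen <- stats::setNames(nchar(genome), names(genome))
  ann <- annotation
  plus <- ann$strand == "+"
  pstart <- ifelse(plus, pmax(0L, ann$start - promoter_length), ann$end)
  pend <- ifelse(plus, ann$start, pmin(clen[ann$contig], ann$end + promoter_length))
  seqs <- substr(genome[ann$contig], pstart + 1L, pend)
  seqs[!plus & pend > pstart] <- revcomp(seqs[!plus & pend > pstart])
  seqs[pend <= pstart] <- ""
  tibble(
    gene_id = ann$gene_id, contig = ann$contig,
    start = as.integer(pstart), end = as.integer(pend),
    strand = ann$strand, sequence = unname(seqs)
  )
}

#' Score one window against a scoring matrix
#'
#' The window score is the sum of the per-position log2 likelihood ratios.
#' Windows containing `N` (or any ambiguous base) score `-Inf` and can never
#' be reported as sites.
#'
#' @param sm A `scoring_matrix`.
#' @param window A DNA string of length `sm$width`.
#' @return The additive score in bits (a single numeric).
#' @export
score_window <- function(sm, window) {
  if (nchar(window) != sm$width) {
    contract_error(paste0("window length ", nchar(window),
                          " does not match matrix width ", sm$width))
  }
  idx <- seq_to_idx(window)
  if (anyNA(idx)) return(-Inf)
  s <- 0
  for (j in seq_len(sm$width)) s <- s + sm$mat[idx[j], j]
  unname(s)
}

rc_matrix <- function(P) {
  out <- P[c("T", "G", "C", "A"), rev(seq_len(ncol(P))), drop = FALSE]
  rownames(out) <- BASES
  out
}

window_scores <- function(P, idx) {
  L <- ncol(P)
  n <- length(idx) - L + 1L
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  na_hit <- logical(n)
  for (j in seq_len(L)) {
    sub <- idx[j:(j + n - 1L)]
    na_hit <- na_hit | is.na(sub)
    v <- P[cbind(sub, rep.int(j, n))]
    v[is.na(v)] <- 0
    s <- s + v
  }
  s[na_hit] <- -Inf
  s
}

#' Scan one promoter for binding sites above a stringency threshold
#'
#' Every window position of the promoter-forward sequence, and of its reverse
#' complement when `config$both_strands`, is scored; the stringency of a
#' window is its score divided by the matrix's maximum achievable score.
#' Sites with stringency strictly greater than the threshold are returned
#' with genomic coordinates on the reference forward strand, sorted by
#' `(start, strand)`.
#'
#' @param sm A `scoring_matrix`.
#' @param promoter A one-row promoter record from [extract_promoters()] (or
#'   any list with fields `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `sequence`).
#' @param config A [scan_config()].
#' @return A tibble of binding sites: `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `score`, `stringency`.
#' @export
scan_promoter <- function(sm, promoter, config = scan_config()) {
  empty <- tibble(gene_id = character(), contig = character(),
                  start = integer(), end = integer(), strand = character(),
                  score = numeric(), stringency = numeric())
  seq <- promoter$sequence
  L <- sm$width
  if (nchar(seq) < L) return(empty)
  idx <- seq_to_idx(seq)
  fwd <- window_scores(sm$mat, idx)
  hits <- list(tibble(offset = seq_along(fwd) - 1L, score = fwd, prom_strand = "+"))
  if (config$both_strands) {
    rc <- window_scores(rc_matrix(sm$mat), idx)
    hits[[2]] <- tibble(offset = seq_along(rc) - 1L, score = rc, prom_strand = "-")
  }
  h <- dplyr::bind_rows(hits)
  h$stringency <- h$score / sm$max_score
  h <- h[is.finite(h$score) & h$stringency > config$stringency_threshold, , drop = FALSE]
  if (nrow(h) == 0) return(empty)
  if (promoter$strand == "+") {
    gstart <- promoter$start + h$offset
    gstrand <- h$prom_strand
  } else {
    gstart <- promoter$end - h$offset - L
    gstrand <- ifelse(h$prom_strand == "+", "-", "+")
  }
  out <- tibble(
    gene_id = promoter$gene_id, contig = promoter$contig,
    start = as.integer(gstart), end = as.integer(gstart + L),
    strand = gstrand, score = h$score, stringency = h$stringency
  )
  dplyr::arrange(out, .data$start, .data$strand)
}

#' Scan all promoters of a genome
#'
#' Convenience wrapper: extracts promoters for every gene and applies
#' [scan_promoter()] to each.
#'
#' @inheritParams extract_promoters
#' @inheritParams scan_promoter
#' @return A tibble of binding sites across all genes (see
#'   [scan_promoter()]).
#' @export
scan_genome <- function(genome, annotation, sm, config = scan_config()) {
  promoters <- extract_promoters(genome, annotation, config$promoter_length)
  res <- purrr::map(seq_len(nrow(promoters)), function(i) {
    scan_promoter(sm, promoters[i, ], config)
  })
  dplyr::bind_rows(res)
}

#' Count distinct binding-site intervals for one gene
#'
#' A self-reverse-complementary motif matches the same genomic interval on
#' both strands; such palindromic double hits count as one site.
#'
#' @param sites Binding-site tibble for a single gene.
#' @return Integer number of distinct `[start, end)` intervals.
#' @export
site_count <- function(sites) {
  if (nrow(sites) == 0) return(0L)
  if (length(unique(sites$gene_id)) > 1) {
    contract_error("site_count expects sites of a single gene; use site_counts()")
  }
  nrow(dplyr::distinct(sites, .data$start, .data$end))
}

#' Per-gene distinct binding-site counts
#'
#' @param sites Binding-site tibble (any number of genes).
#' @return Tibble with columns `gene_id`, `n_sites` (distinct intervals per
#'   gene; strand-duplicate hits on the same interval count once).
#' @export
site_counts <- function(sites) {
  if (nrow(sites) == 0) return(tibble(gene_id = character(), n_sites = integer()))
  sites %>%
    dplyr::distinct(.data$gene_id, .data$start, .data$end) %>%
    dplyr::count(.data$gene_id, name = "n_sites")
}

#' Genes with at least one binding site
#'
#' @param sites Binding-site tibble from [scan_genome()].
#' @return Character vector of gene identifiers with `n_sites >= 1`, sorted.
#' @export
genes_with_sites <- function(sites) {
  sort(unique(sites$gene_id))
}

#' Packaged example binding-site frequency matrix
#'
#' A 19-position matrix for an inverted-repeat Zn2Cys6-type site with the
#' palindromic core TCGG, an 11-nucleotide spacer, and CCGA: consensus bases
#' carry frequency 0.85 in the core columns and the spacer columns are at
#' background (0.25 each). The non-consensus core frequencies are assigned
#' complement-symmetrically, so the whole matrix is exactly its own reverse
#' complement — a forward hit is always mirrored by an equal-scoring hit on
#' the opposite strand over the same interval.
#'
#' @param spacer_length Length of the unconstrained spacer between the two
#'   half-sites. Default 11.
#' @return A `frequency_matrix` object.
#' @export
example_site_matrix <- function(spacer_length = 11) {
  col_for <- function(base) {
    switch(base,
      T = c(A = 0.03, C = 0.07, G = 0.05, T = 0.85),
      A = c(A = 0.85, C = 0.05, G = 0.07, T = 0.03),
      C = c(A = 0.07, C = 0.85, G = 0.03, T = 0.05),
      G = c(A = 0.05, C = 0.03, G = 0.85, T = 0.07)
    )
  }
  core5 <- c("T", "C", "G", "G")
  core3 <- c("C", "C", "G", "A")
  cols <- c(lapply(core5, col_for),
            rep(list(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)), spacer_length),
            lapply(core3, col_for))
  frequency_matrix(do.call(cbind, cols))
}
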