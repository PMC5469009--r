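#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

format_error <- function(msg, ...) {
  abort(msg, class = "regulonscan_format_error", ...)
}

contract_error <- function(msg, ...) {
  abort(msg, class = "regulonscan_contract_error", ...)
}

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased and contig names are taken as the first
#' whitespace-delimited token of each header line. Only the DNA alphabet
#' `A, C, G, T, N` (either case) is accepted.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector mapping contig name to sequence, in file
#'   order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 chromosome", "acgtACGT"), fa)
#' read_genome(fa)
read_genome <- function(path) {
  if (!file.exists(path)) format_error(paste0("file does not exist: ", path))
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) format_error(paste0("cannot parse FASTA '", path, "': ", conditionMessage(e)))
  )
  if (length(seqs) == 0) format_error(paste0("empty FASTA file: ", path))
  nm <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    format_error(paste0("duplicate contig name in '", path, "': ",
                        nm[duplicated(nm)][1]))
  }
  x <- toupper(as.character(seqs))
  if (any(nchar(x) == 0)) {
    format_error(paste0("record with no sequence in '", path, "': ", nm[nchar(x) == 0][1]))
  }
  bad <- stringr::str_detect(x, "[^ACGTN]")
  if (any(bad)) {
    ch <- stringr::str_extract(x[bad][1], "[^ACGTN]")
    format_error(paste0("illegal character '", ch, "' in contig ", nm[bad][1]))
  }
  stats::setNames(x, nm)
}

#' Read gene models from GFF3 or BED6
#'
#' Coordinates are normalized to the package-internal 0-based half-open
#' convention (GFF3 is 1-based inclusive on disk; BED is already 0-based
#' half-open). For GFF3 only rows of type `gene` are kept and the `ID`
#' attribute becomes the gene identifier; for BED6 the name column does.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file. The format is chosen
#'   by file extension.
#' @return A tibble with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand` (0-based half-open, strand `+` or `-`).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) format_error(paste0("file does not exist: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- tryCatch(
      rtracklayer::import(path, format = "gff3"),
      error = function(e) format_error(paste0("cannot parse GFF3 '", path, "': ", conditionMessage(e)))
    )
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0) format_error(paste0("no 'gene' rows in GFF3 file: ", path))
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids)) format_error("GFF3 gene row without an ID attribute")
    ann <- tibble(
      gene_id = as.character(ids),
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  } else if (ext == "bed") {
    raw <- tryCatch(
      readr::read_tsv(path, col_names = FALSE, comment = "#", show_col_types = FALSE,
                      col_types = readr::cols(.default = readr::col_character())),
      error = function(e) format_error(paste0("cannot parse BED '", path, "': ", conditionMessage(e)))
    )
    if (ncol(raw) < 6) format_error(paste0("BED6 requires 6 columns, got ", ncol(raw)))
    ann <- tibble(
      gene_id = raw[[4]],
      contig = raw[[1]],
      start = as.integer(raw[[2]]),
      end = as.integer(raw[[3]]),
      strand = raw[[6]]
    )
  } else {
    format_error(paste0("unknown annotation format (expect .gff3/.gff/.bed): ", path))
  }
  if (any(!ann$strand %in% c("+", "-"))) {
    format_error(paste0("missing or invalid strand for gene ",
                        ann$gene_id[!ann$strand %in% c("+", "-")][1]))
  }
  if (any(ann$start >= ann$end)) {
    format_error(paste0("start >= end for gene ", ann$gene_id[ann$start >= ann$end][1]))
  }
  if (anyDuplicated(ann$gene_id)) {
    format_error(paste0("duplicate gene_id: ", ann$gene_id[duplicated(ann$gene_id)][1]))
  }
  ann
}

#' Parse a sample name of the form strain.condition.repN
#' @noRd
parse_sample_names <- function(x) {
  parts <- stringr::str_match(x, "^([^.]+)\\.([^.]+)\\.rep(\\d+)$")
  if (anyNA(parts[, 1])) {
    format_error(paste0("sample name not of the form strain.condition.repN: ",
                        x[is.na(parts[, 1])][1]))
  }
  tibble(sample = x, strain = parts[, 2], condition = parts[, 3],
         replicate = as.integer(parts[, 4]))
}

#' Read a replicated FPKM expression table
#'
#' The on-disk format is a TSV whose first column holds gene identifiers and
#' whose remaining column headers encode the design as
#' `strain.condition.repN` (for example `WT.pectin.rep1`). The in-memory
#' representation is a long tibble, one row per gene and sample.
#'
#' @param path Path to the TSV file. Lines starting with `#` are ignored.
#' @return A tibble with columns `gene_id`, `strain`, `condition`,
#'   `replicate`, `fpkm`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) format_error(paste0("file does not exist: ", path))
  raw <- tryCatch(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character())),
    error = function(e) format_error(paste0("cannot parse TSV '", path, "': ", conditionMessage(e)))
  )
  if (ncol(raw) < 2) format_error("expression table needs a gene_id column and at least one sample")
  gene_ids <- raw[[1]]
  if (anyDuplicated(gene_ids)) {
    row <- which(duplicated(gene_ids))[1]
    format_error(paste0("duplicate gene '", gene_ids[row], "' at row ", row))
  }
  design <- parse_sample_names(names(raw)[-1])
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw))
  if (anyNA(vals)) {
    row <- which(rowSums(is.na(vals)) > 0)[1]
    format_error(paste0("non-numeric expression value at row ", row))
  }
  if (any(vals < 0)) {
    row <- which(rowSums(vals < 0) > 0)[1]
    format_error(paste0("negative FPKM value at row ", row))
  }
  long <- tibble(
    gene_id = rep(gene_ids, times = ncol(vals)),
    sample = rep(design$sample, each = length(gene_ids)),
    fpkm = as.vector(vals)
  )
  out <- dplyr::left_join(long, design, by = "sample")
  dplyr::select(out, "gene_id", "strain", "condition", "replicate", "fpkm")
}

#' Write a replicated FPKM expression table
#'
#' Inverse of [read_expression()]: pivots the long tibble back to the wide
#' genes-by-samples TSV with `strain.condition.repN` headers.
#'
#' @param expr Long expression tibble as returned by [read_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  wide <- expr %>%
    dplyr::mutate(sample = paste0(.data$strain, ".", .data$condition, ".rep", .data$replicate)) %>%
    dplyr::select("gene_id", "sample", "fpkm") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "fpkm")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Write binding sites as BED6
#'
#' The BED score column is `round(1000 * stringency)`; the name column is the
#' gene the promoter belongs to. Coordinates are written 0-based half-open,
#' as BED requires.
#'
#' @param sites Tibble of binding sites with columns `gene_id`, `contig`,
#'   `start`, `end`, `strand`, `stringency`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  if (nrow(sites) > 0 && any(sites$stringency < -1 | sites$stringency > 1)) {
    contract_error("stringency outside [-1, 1] cannot be written as a BED score")
  }
  bed <- tibble(
    contig = sites$contig,
    start = sites$start,
    end = sites$end,
    name = sites$gene_id,
    score = as.integer(round(1000 * sites$stringency)),
    strand = sites$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read binding sites from a BED6 file written by [write_sites_bed()]
#'
#' @param path Path to the BED6 file.
#' @return Tibble with columns `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `stringency` (score column divided by 1000).
#' @export
read_sites_bed <- function(path) {
  if (!file.exists(path)) format_error(paste0("file does not exist: ", path))
  if (file.size(path) == 0) {
    return(tibble(gene_id = character(), contig = character(),
                  start = integer(), end = integer(),
                  strand = character(), stringency = numeric()))
  }
  raw <- readr::read_tsv(path, col_names = c("contig", "start", "end", "name", "score", "strand"),
                         show_col_types = FALSE,
                         col_types = "ciicic")
  tibble(gene_id = raw$name, contig = raw$contig, start = raw$start,
         end = raw$end, strand = raw$strand, stringency = raw$score / 1000)
}

#' Read a gene-to-category annotation catalog
#'
#' The catalog format is a two- or three-column TSV: `gene_id`,
#' `category_id`, and optionally `label`. Category identifiers follow the
#' dotted hierarchical grammar of functional catalogues (for example
#' `01.05.03.06.07.02`), where each dot-separated prefix is an ancestor
#' category.
#'
#' @param path Path to the TSV file. Lines starting with `#` are ignored.
#' @return A tibble with columns `gene_id`, `category_id` and `label`
#'   (`NA` when absent).
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) format_error(paste0("file does not exist: ", path))
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("gene_id", "category_id") %in% names(raw))) {
    format_error("catalog TSV needs columns gene_id and category_id")
  }
  check_category_ids(raw$category_id)
  if (!"label" %in% names(raw)) raw$label <- NA_character_
  dplyr::select(raw, "gene_id", "category_id", "label")
}

check_category_ids <- function(ids) {
  ok <- stringr::str_detect(ids, "^\\d+(\\.\\d+)*$")
  if (!all(ok)) {
    format_error(paste0("malformed category ID (expect dotted integers): ", ids[!ok][1]))
  }
  invisible(ids)
}

#' Write a frequency or scoring matrix to TSV
#'
#' Four rows labeled A, C, G, T with one tab-separated column per motif
#' position; lines starting with `#` are comments.
#'
#' @param m A 4-by-L numeric matrix with rownames `A, C, G, T`, or a
#'   [frequency_matrix()]/scoring-matrix object (its `mat` field is written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  if (is.list(m) && !is.null(m$mat)) m <- m$mat
  stopifnot(is.matrix(m), nrow(m) == 4)
  lines <- vapply(c("A", "C", "G", "T"), function(b) {
    paste(c(b, format(m[b, ], digits = 15, trim = TRUE, scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a base-frequency matrix from TSV
#'
#' @param path Path to a 4-row, base-labeled, tab-separated matrix file as
#'   written by [write_matrix_tsv()].
#' @return A 4-by-L numeric matrix with rownames `A, C, G, T`.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) format_error(paste0("file does not exist: ", path))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) != 4) format_error("matrix file must have exactly 4 non-comment rows")
  parts <- strsplit(lines, "\t")
  bases <- vapply(parts, `[`, character(1), 1L)
  if (!setequal(bases, c("A", "C", "G", "T"))) {
    format_error("matrix rows must be labeled A, C, G, T")
  }
  L <- length(parts[[1]]) - 1L
  if (L < 1 || any(lengths(parts) != L + 1L)) format_error("ragged matrix rows")
  m <- matrix(NA_real_, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]][-1]))
    if (anyNA(v)) format_error(paste0("non-numeric matrix entry in row ", bases[i]))
    m[bases[i], ] <- v
  }
  m
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
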