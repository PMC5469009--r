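#' Configuration for a synthetic regulon study
#'
#' Defines the conditions a simulated study emulates: a wild-type and a
#' regulator-deletion strain profiled in replicate across a no-carbon
#' reference, a repressing sugar, and two inducing carbon sources; promoters
#' carrying planted binding sites for a subset of genes; and a functional
#' catalog in which the regulon is enriched. Defaults give 100 genes of which
#' 15 form the planted core regulon (both a promoter site and an activated
#' expression response), 10 carry sites without an expression response, and
#' 8 respond (as factor-repressed genes) without a site.
#'
#' @param seed Integer seed; mandatory. The whole study is generated from a
#'   single pseudo-random stream keyed by it.
#' @param n_genes Number of genes. Default 100.
#' @param gene_length Gene body length in bp. Default 500.
#' @param promoter_length Upstream promoter length in bp. Default 1000.
#' @param gc_content Background GC fraction. Default 0.5.
#' @param n_core Genes planted with both sites and an activated response.
#' @param n_sites_only Genes planted with sites but background expression.
#' @param n_affected_only Genes with a repressed expression response and no
#'   site.
#' @param sites_per_gene Integer vector sampled from for the number of
#'   planted sites per motif-bearing gene. Default `1:3`.
#' @param target_stringency_range Range planted target stringencies are
#'   drawn from. Default `c(0.8, 1)`.
#' @param fold_change Expression effect size of responsive genes. Default 8.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline FPKM
#'   parameters. Defaults `log(50)` and 1.
#' @param noise_sd Replicate noise standard deviation on the log2 scale.
#'   Default 0.2.
#' @param replicates Replicates per strain/condition cell. Default 3.
#' @param enriched_category Dotted category ID planted as enriched in the
#'   responsive genes.
#' @param annotated_fraction Fraction of responsive genes annotated to the
#'   enriched category. Default 0.9.
#' @param site_matrix `frequency_matrix` used for planting and scanning.
#'   Default [example_site_matrix()].
#' @param background_stringency_cap Background promoter windows with
#'   stringency above this value are redrawn during generation, keeping
#'   planted-site recovery sharp. Default 0.55.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_genes = 100,
                              gene_length = 500,
                              promoter_length = 1000,
                              gc_content = 0.5,
                              n_core = 15,
                              n_sites_only = 10,
                              n_affected_only = 8,
                              sites_per_gene = 1:3,
                              target_stringency_range = c(0.8, 1),
                              fold_change = 8,
                              baseline_meanlog = log(50),
                              baseline_sdlog = 1,
                              noise_sd = 0.2,
                              replicates = 3,
                              enriched_category = "01.05.03.06.07.02",
                              annotated_fraction = 0.9,
                              site_matrix = example_site_matrix(),
                              background_stringency_cap = 0.55) {
  if (missing(seed)) contract_error("a seed is mandatory for simulation")
  if (gc_content <= 0 || gc_content >= 1) contract_error("gc_content must be in (0, 1)")
  if (annotated_fraction < 0 || annotated_fraction > 1) {
    contract_error("annotated_fraction must be in [0, 1]")
  }
  if (any(target_stringency_range <= 0.6) || any(target_stringency_range > 1)) {
    contract_error("target stringencies must lie in (0.6, 1]")
  }
  if (n_core + n_sites_only + n_affected_only > n_genes) {
    contract_error("role counts exceed n_genes")
  }
  structure(as.list(environment()), class = "simulation_config")
}

sim_background_freqs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

draw_bases <- function(n, b) {
  paste(sample(BASES, n, replace = TRUE, prob = b), collapse = "")
}

#' Plant a binding site of a target stringency into a promoter sequence
#'
#' Writes the matrix's highest-scoring sequence at the given offset, then
#' greedily degrades it one position at a time — always applying the single
#' substitution with the smallest score drop — while the degraded site still
#' meets the target. The realized stringency is therefore the smallest value
#' `>= target_stringency` the matrix's score lattice can express. Sites
#' planted on the `-` strand are reverse-complemented before insertion.
#'
#' @param sequence Promoter sequence (promoter-forward orientation).
#' @param sm A `scoring_matrix`.
#' @param target_stringency Target in (0, 1].
#' @param strand `"+"` or `"-"`: orientation of the planted site relative to
#'   `sequence`.
#' @param offset 0-based position of the site within `sequence`.
#' @return List with `sequence` (modified), `realized_stringency`, and
#'   `site_seq` (the site in matrix orientation).
#' @export
plant_site <- function(sequence, sm, target_stringency, strand = "+", offset = 0) {
  L <- sm$width
  if (target_stringency > 1) contract_error("target_stringency cannot exceed 1")
  if (offset < 0 || offset + L > nchar(sequence)) {
    contract_error("planted site does not fit within the promoter")
  }
  P <- sm$mat
  site <- strsplit(argmax_sequence(sm), NULL)[[1]]
  score <- sm$max_score
  repeat {
    drops <- expand.grid(j = seq_len(L), b = BASES, stringsAsFactors = FALSE)
    drops$drop <- P[cbind(match(site[drops$j], BASES), drops$j)] -
      P[cbind(match(drops$b, BASES), drops$j)]
    drops <- drops[drops$drop > 0, , drop = FALSE]
    if (nrow(drops) == 0) break
    drops <- drops[order(drops$drop, drops$j, match(drops$b, BASES)), , drop = FALSE]
    cand <- drops[1, ]
    if ((score - cand$drop) / sm$max_score >= target_stringency) {
      site[cand$j] <- cand$b
      score <- score - cand$drop
    } else {
      break
    }
  }
  site_str <- paste(site, collapse = "")
  insert <- if (strand == "-") revcomp(site_str) else site_str
  substr(sequence, offset + 1, offset + L) <- insert
  list(sequence = sequence, realized_stringency = score / sm$max_score,
       site_seq = site_str)
}

scrub_region <- function(seq_chars, from, to, sm, b, cap, protect, max_iter = 100) {
  # redraw background bases until no window in [from, to) exceeds the
  # stringency cap on either strand; positions in `protect` are never touched
  L <- sm$width
  for (iter in seq_len(max_iter)) {
    region <- paste(seq_chars[from:(to - 1L)], collapse = "")
    idx <- seq_to_idx(region)
    s <- pmax(window_scores(sm$mat, idx), window_scores(rc_matrix(sm$mat), idx))
    hot <- which(s / sm$max_score > cap)
    if (length(hot) == 0) return(seq_chars)
    pos <- unique(unlist(lapply(hot, function(i) (from + i - 2L) + seq_len(L))))
    pos <- setdiff(pos, protect)
    if (length(pos) == 0) return(seq_chars)
    seq_chars[pos] <- sample(BASES, length(pos), replace = TRUE, prob = b)
  }
  contract_error("could not scrub background promoter windows below the stringency cap")
}

#' Simulate a genome with annotated genes and planted promoter sites
#'
#' Generates i.i.d. background bases at the configured GC content on a
#' single contig, places non-overlapping genes (alternating strand) with at
#' least a full promoter length of clearance, scrubs chance near-threshold
#' windows out of the promoters, and plants binding sites per the
#' configuration's role plan. The scoring matrix used for planting is built
#' from the configured site matrix and the GC-implied background, and is
#' returned so that realized stringencies can be recomputed exactly.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (named character vector), `annotation`
#'   (tibble), `scoring_matrix`, `background` (the GC-implied frequencies),
#'   `roles` (tibble `gene_id`, `role`), and `truth_sites` (tibble
#'   `gene_id`, `contig`, `start`, `end`, `strand`, `offset`,
#'   `target_stringency`, `realized_stringency`, `site_seq`).
#' @export
simulate_genome <- function(config) {
  withr::with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  n <- config$n_genes
  Lp <- config$promoter_length
  Lg <- config$gene_length
  b <- sim_background_freqs(config$gc_content)
  sm <- log_likelihood_transform(config$site_matrix, b)
  L <- sm$width
  if (Lp < L) contract_error("promoter_length is shorter than the motif")

  slot <- Lg + 2L * Lp + 100L
  contig_len <- n * slot
  gene_start <- (seq_len(n) - 1L) * slot + Lp
  strand <- rep(c("+", "-"), length.out = n)
  ann <- tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    contig = "contig_1",
    start = as.integer(gene_start),
    end = as.integer(gene_start + Lg),
    strand = strand
  )
  if (max(ann$end) + Lp > contig_len) contract_error("genes do not fit on the contig")

  seq_chars <- sample(BASES, contig_len, replace = TRUE, prob = b)

  roles <- assign_roles(config)
  with_sites <- roles$gene_id[roles$role %in% c("core", "sites_only")]

  proms <- tibble(
    gene_id = ann$gene_id,
    pstart = ifelse(ann$strand == "+", ann$start - Lp, ann$end),
    pend = ifelse(ann$strand == "+", ann$start, ann$end + Lp)
  )

  # scrub chance hits from every promoter before planting
  for (i in seq_len(nrow(proms))) {
    seq_chars <- scrub_region(seq_chars, proms$pstart[i] + 1L, proms$pend[i] + 1L,
                              sm, b, config$background_stringency_cap,
                              protect = integer(0))
  }

  truth <- list()
  for (g in with_sites) {
    row <- which(proms$gene_id == g)
    pstart <- proms$pstart[row]
    pend <- proms$pend[row]
    gstrand <- ann$strand[row]
    k <- sample(config$sites_per_gene, 1)
    occupied <- integer(0)
    for (s in seq_len(k)) {
      offset <- NA_integer_
      for (try in 1:200) {
        cand <- sample.int(Lp - L + 1L, 1) - 1L
        if (!any(abs(cand - occupied) < L)) { offset <- cand; break }
      }
      if (is.na(offset)) next
      occupied <- c(occupied, offset)
      target <- stats::runif(1, config$target_stringency_range[1],
                             config$target_stringency_range[2])
      site_strand <- sample(c("+", "-"), 1)
      # promoter-forward sequence for this gene
      region <- paste(seq_chars[(pstart + 1L):pend], collapse = "")
      pf <- if (gstrand == "+") region else revcomp(region)
      planted <- plant_site(pf, sm, target, site_strand, offset)
      back <- if (gstrand == "+") planted$sequence else revcomp(planted$sequence)
      seq_chars[(pstart + 1L):pend] <- strsplit(back, NULL)[[1]]
      if (gstrand == "+") {
        site_start <- pstart + offset
        genomic_strand <- site_strand
      } else {
        site_start <- pend - offset - L
        genomic_strand <- if (site_strand == "+") "-" else "+"
      }
      truth[[length(truth) + 1]] <- tibble(
        gene_id = g, contig = "contig_1",
        start = as.integer(site_start), end = as.integer(site_start + L),
        strand = genomic_strand, offset = as.integer(offset),
        target_stringency = target,
        realized_stringency = planted$realized_stringency,
        site_seq = planted$site_seq
      )
    }
  }
  truth_sites <- dplyr::bind_rows(truth)

  genome <- stats::setNames(paste(seq_chars, collapse = ""), "contig_1")
  list(genome = genome, annotation = ann, scoring_matrix = sm,
       background = b, roles = roles, truth_sites = truth_sites)
}

assign_roles <- function(config) {
  n <- config$n_genes
  ids <- sprintf("g%03d", seq_len(n))
  pool <- sample(ids)
  role <- rep("background", n)
  names(role) <- ids
  role[pool[seq_len(config$n_core)]] <- "core"
  role[pool[config$n_core + seq_len(config$n_sites_only)]] <- "sites_only"
  role[pool[config$n_core + config$n_sites_only +
              seq_len(config$n_affected_only)]] <- "affected_only"
  tibble(gene_id = ids, role = unname(role[ids]))
}

role_fold <- function(role, strain, condition, fold) {
  # core genes: activated by the factor (induced in WT on the inducing
  # carbon sources, not in the mutant); affected_only genes: repressed
  # (de-repressed in the mutant on pectin); everything else flat
  dplyr::case_when(
    role == "core" & strain == "WT" & condition %in% c("rha", "pectin") ~ fold,
    role == "affected_only" & strain == "mutant" & condition == "pectin" ~ fold,
    startsWith(role, "cell:") &
      paste(strain, condition, sep = ".") == sub("^cell:", "", role) ~ fold,
    TRUE ~ 1
  )
}

#' Simulate a replicated two-strain, four-condition FPKM matrix
#'
#' Each gene draws a log-normal baseline FPKM; responsive genes multiply it
#' by the configured fold change in their responsive cells (activated core
#' genes: wild type on the inducing sugars; repressed genes: the mutant on
#' pectin). Per-replicate noise is log-normal with the configured log2-scale
#' standard deviation. Roles of the form `"cell:STRAIN.CONDITION"` place a
#' gene's response in an arbitrary single cell, which supports
#' cluster-recovery designs.
#'
#' @param config A [simulation_config()].
#' @param roles Optional roles tibble (`gene_id`, `role`); defaults to the
#'   configuration's role assignment.
#' @return List with `expr` (long tibble `gene_id`, `strain`, `condition`,
#'   `replicate`, `fpkm`) and `truth` (tibble `gene_id`, `role`,
#'   `baseline_fpkm`).
#' @export
simulate_expression <- function(config, roles = NULL) {
  withr::with_seed(config$seed + 1L, simulate_expression_impl(config, roles))
}

simulate_expression_impl <- function(config, roles = NULL) {
  if (is.null(roles)) roles <- assign_roles(config)
  bad <- setdiff(unique(roles$role),
                 c("core", "sites_only", "affected_only", "background"))
  bad <- bad[!startsWith(bad, "cell:")]
  if (length(bad) > 0) contract_error(paste0("invalid role: ", bad[1]))
  baseline <- stats::rlnorm(nrow(roles), config$baseline_meanlog,
                            config$baseline_sdlog)
  design <- tidyr::expand_grid(
    strain = c("WT", "mutant"),
    condition = c("NoC", "sucrose", "rha", "pectin"),
    replicate = seq_len(config$replicates)
  )
  grid <- tidyr::expand_grid(
    dplyr::mutate(roles, baseline = baseline), design
  )
  noise <- stats::rnorm(nrow(grid), 0, config$noise_sd * log(2))
  expr <- grid %>%
    dplyr::mutate(
      fold = role_fold(.data$role, .data$strain, .data$condition,
                       config$fold_change),
      fpkm = .data$baseline * .data$fold * exp(noise)
    ) %>%
    dplyr::select("gene_id", "strain", "condition", "replicate", "fpkm")
  list(expr = expr,
       truth = tibble(gene_id = roles$gene_id, role = roles$role,
                      baseline_fpkm = baseline))
}

#' Simulate a hierarchical functional-category catalog
#'
#' Responsive genes (roles `core` and `affected_only`) are annotated to the
#' configured enriched leaf category at the configured fraction; every gene
#' additionally receives one decoy category drawn uniformly, so decoys are
#' not enriched beyond chance.
#'
#' @param config A [simulation_config()].
#' @param roles Roles tibble (`gene_id`, `role`).
#' @return List with `catalog` (tibble `gene_id`, `category_id`, `label`)
#'   and `truth` (list with `enriched_category` and the annotated genes).
#' @export
simulate_catalog <- function(config, roles) {
  withr::with_seed(config$seed + 2L, simulate_catalog_impl(config, roles))
}

simulate_catalog_impl <- function(config, roles) {
  decoys <- c("02.01", "02.07", "10.03", "14.07", "20.01", "32.05")
  regulon_genes <- roles$gene_id[roles$role %in% c("core", "affected_only")]
  n_annot <- round(config$annotated_fraction * length(regulon_genes))
  annotated <- if (n_annot > 0) sort(sample(regulon_genes, n_annot)) else character(0)
  enriched <- tibble(
    gene_id = annotated,
    category_id = config$enriched_category,
    label = "planted enriched category"
  )
  decoy <- tibble(
    gene_id = roles$gene_id,
    category_id = sample(decoys, nrow(roles), replace = TRUE),
    label = NA_character_
  )
  catalog <- dplyr::bind_rows(enriched, decoy) %>%
    dplyr::arrange(.data$gene_id, .data$category_id)
  list(catalog = catalog,
       truth = list(enriched_category = config$enriched_category,
                    annotated_genes = annotated))
}

#' Simulate a complete regulon study
#'
#' Runs [simulate_genome()], [simulate_expression()] and
#' [simulate_catalog()] under one seed and bundles their outputs with the
#' ground-truth tables for every stage.
#'
#' @param config A [simulation_config()].
#' @return List with `genome`, `annotation`, `scoring_matrix`, `background`,
#'   `expr`, `catalog`, `config`, and `truth` (list: `sites`, `roles`,
#'   `enriched_category`, `core_genes`).
#' @export
simulate_study <- function(config) {
  gen <- simulate_genome(config)
  ex <- simulate_expression(config, gen$roles)
  cat <- simulate_catalog(config, gen$roles)
  list(
    genome = gen$genome, annotation = gen$annotation,
    scoring_matrix = gen$scoring_matrix, background = gen$background,
    expr = ex$expr, catalog = cat$catalog, config = config,
    truth = list(
      sites = gen$truth_sites,
      roles = dplyr::left_join(gen$roles,
                               dplyr::select(ex$truth, "gene_id", "baseline_fpkm"),
                               by = "gene_id"),
      enriched_category = cat$truth$enriched_category,
      core_genes = sort(gen$roles$gene_id[gen$roles$role == "core"])
    )
  )
}

#' Write a simulated study to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `expr.tsv`, `catalog.tsv`, `matrix.tsv`
#' and `truth/*.tsv` into a directory; every file round-trips through the
#' package readers.
#'
#' @param sim Output of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                              file.path(outdir, "genome.fa"))
  gr <- GenomicRanges::GRanges(
    seqnames = sim$annotation$contig,
    ranges = IRanges::IRanges(start = sim$annotation$start + 1L,
                              end = sim$annotation$end),
    strand = sim$annotation$strand
  )
  gr$type <- "gene"
  gr$ID <- sim$annotation$gene_id
  rtracklayer::export(gr, file.path(outdir, "genes.gff3"), format = "gff3")
  write_expression(sim$expr, file.path(outdir, "expr.tsv"))
  readr::write_tsv(sim$catalog, file.path(outdir, "catalog.tsv"))
  write_matrix_tsv(sim$config$site_matrix, file.path(outdir, "matrix.tsv"))
  readr::write_tsv(sim$truth$sites, file.path(outdir, "truth", "sites.tsv"))
  readr::write_tsv(sim$truth$roles, file.path(outdir, "truth", "roles.tsv"))
  invisible(outdir)
}
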