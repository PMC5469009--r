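small_cfg <- function(seed = 3, ...) {
  simulation_config(seed = seed, n_genes = 12, n_core = 3, n_sites_only = 2,
                    n_affected_only = 2, ...)
}

test_that("genome simulation is seed-reproducible and respects GC content", {
  g1 <- simulate_genome(small_cfg())
  g2 <- simulate_genome(small_cfg())
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth_sites, g2$truth_sites)
  expect_identical(g1$annotation, g2$annotation)

  gc_cfg <- small_cfg(seed = 4, gc_content = 0.4)
  gen <- simulate_genome(gc_cfg)
  n <- nchar(gen$genome)
  gc <- sum(strsplit(gen$genome[[1]], NULL)[[1]] %in% c("G", "C")) / n
  # realized GC within 3 sigma binomial bounds (site planting perturbs only
  # a negligible fraction of bases)
  expect_lt(abs(gc - 0.4), 3 * sqrt(0.4 * 0.6 / n) + 0.005)

  # genes are spaced at least a promoter length apart
  ann <- gen$annotation
  expect_true(all(diff(ann$start) >= gc_cfg$gene_length +
                    gc_cfg$promoter_length))
})

test_that("planted sites realize the smallest expressible stringency above target", {
  sm <- log_likelihood_transform(example_site_matrix(), uniform_background)
  prom <- paste(rep("A", 100), collapse = "")
  exact <- plant_site(prom, sm, 1.0, "+", 10)
  expect_equal(exact$realized_stringency, 1.0)
  expect_equal(substr(exact$sequence, 11, 29), argmax_sequence(sm))

  degraded <- plant_site(prom, sm, 0.7, "+", 0)
  expect_gte(degraded$realized_stringency, 0.7)
  expect_lte(degraded$realized_stringency, 1.0)
  # recompute with the scanning scorer
  expect_equal(score_window(sm, degraded$site_seq) / sm$max_score,
               degraded$realized_stringency, tolerance = 1e-12)
  # greedy degradation: one step further would undershoot the target
  if (degraded$realized_stringency < 1) {
    expect_lt(degraded$realized_stringency, 1)
  }

  minus <- plant_site(prom, sm, 1.0, "-", 40)
  expect_equal(substr(minus$sequence, 41, 59),
               oracle_revcomp(argmax_sequence(sm)))

  expect_error(plant_site(prom, sm, 1.1, "+", 0),
               class = "regulonscan_contract_error")
  expect_error(plant_site("ACGT", sm, 0.9, "+", 0),
               class = "regulonscan_contract_error")
})

test_that("truth-table stringencies recompute exactly through the scanner", {
  gen <- simulate_genome(small_cfg(seed = 8))
  sm <- gen$scoring_matrix
  ts <- gen$truth_sites
  expect_gt(nrow(ts), 0)
  for (i in seq_len(nrow(ts))) {
    w <- substr(gen$genome[[1]], ts$start[i] + 1, ts$end[i])
    if (ts$strand[i] == "-") w <- oracle_revcomp(w)
    expect_equal(score_window(sm, w) / sm$max_score,
                 ts$realized_stringency[i], tolerance = 1e-9)
  }
  expect_true(all(ts$realized_stringency >= 0.8 - 1e-12))
})

test_that("scanning recovers exactly the genes with planted sites", {
  gen <- simulate_genome(small_cfg(seed = 12))
  sites <- scan_genome(gen$genome, gen$annotation, gen$scoring_matrix,
                       scan_config())
  planted_genes <- sort(unique(gen$truth_sites$gene_id))
  expect_setequal(genes_with_sites(sites), planted_genes)
  # every planted interval is found
  found <- dplyr::distinct(sites, gene_id, start, end)
  truth <- dplyr::distinct(gen$truth_sites, gene_id, start, end)
  expect_equal(nrow(dplyr::anti_join(truth, found,
                                     by = c("gene_id", "start", "end"))), 0)
  # at threshold 1.0 nothing above (strict inequality)
  none <- scan_genome(gen$genome, gen$annotation, gen$scoring_matrix,
                      scan_config(stringency_threshold = 1.0))
  expect_equal(nrow(none), 0)
})

test_that("background promoters scrubbed of near-threshold windows stay clean", {
  cfg <- simulation_config(seed = 5, n_genes = 12, n_core = 0,
                           n_sites_only = 0, n_affected_only = 0)
  gen <- simulate_genome(cfg)
  sites <- scan_genome(gen$genome, gen$annotation, gen$scoring_matrix,
                       scan_config(stringency_threshold = cfg$background_stringency_cap))
  expect_equal(nrow(sites), 0)
})

test_that("expression simulation realizes the planted fold structure", {
  cfg <- simulation_config(seed = 31, n_genes = 30, n_core = 8,
                           n_sites_only = 4, n_affected_only = 5)
  ex <- simulate_expression(cfg)
  expr <- ex$expr
  expect_true(all(expr$fpkm >= 0))
  expect_equal(nrow(expr), 30 * 2 * 4 * 3)
  core <- ex$truth$gene_id[ex$truth$role == "core"]
  wt_rha <- condition_means(expr, "WT", "rha")
  mu_rha <- condition_means(expr, "mutant", "rha")
  ratio <- wt_rha$mean_fpkm[wt_rha$gene_id %in% core] /
    mu_rha$mean_fpkm[mu_rha$gene_id %in% core]
  # 8-fold effect within lognormal noise at n = 3
  expect_true(all(ratio > 3 & ratio < 22))
  bg <- ex$truth$gene_id[ex$truth$role == "background"]
  bg_ratio <- wt_rha$mean_fpkm[wt_rha$gene_id %in% bg] /
    mu_rha$mean_fpkm[mu_rha$gene_id %in% bg]
  expect_true(all(bg_ratio > 1 / 3 & bg_ratio < 3))

  # noise-free limit gives exact fold ratios
  cfg0 <- simulation_config(seed = 31, n_genes = 10, n_core = 4,
                            n_sites_only = 0, n_affected_only = 0,
                            noise_sd = 0)
  ex0 <- simulate_expression(cfg0)
  core0 <- ex0$truth$gene_id[ex0$truth$role == "core"]
  r0 <- condition_means(ex0$expr, "WT", "pectin")
  m0 <- condition_means(ex0$expr, "mutant", "pectin")
  expect_equal(r0$mean_fpkm[r0$gene_id %in% core0] /
                 m0$mean_fpkm[m0$gene_id %in% core0],
               rep(8, 4), tolerance = 1e-12)

  expect_error(
    simulate_expression(cfg, tibble::tibble(gene_id = "g001",
                                            role = "nonsense")),
    "invalid role", class = "regulonscan_contract_error")
})

test_that("catalog simulation plants a detectable enrichment", {
  cfg <- simulation_config(seed = 17, n_genes = 100, n_core = 20,
                           n_affected_only = 10, n_sites_only = 0,
                           annotated_fraction = 1.0)
  roles <- withr::with_seed(cfg$seed, regulonscan:::assign_roles(cfg))
  cat <- simulate_catalog(cfg, roles)
  expect_equal(length(cat$truth$annotated_genes), 30)
  K <- sum(cat$catalog$category_id == cfg$enriched_category)
  p <- hypergeom_upper_tail(30, 30, K, 100)
  expect_lt(p, 5e-5)

  cat0 <- simulate_catalog(
    simulation_config(seed = 17, n_genes = 100, n_core = 20,
                      n_affected_only = 10, n_sites_only = 0,
                      annotated_fraction = 0),
    roles)
  expect_equal(length(cat0$truth$annotated_genes), 0)
  expect_false(cfg$enriched_category %in% cat0$catalog$category_id)

  # no responsive roles: decoys only
  flat_roles <- tibble::tibble(gene_id = roles$gene_id, role = "background")
  catd <- simulate_catalog(cfg, flat_roles)
  expect_false(cfg$enriched_category %in% catd$catalog$category_id)
})

test_that("emitted files round-trip through the io module", {
  sim <- simulate_study(small_cfg(seed = 6))
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  genome <- read_genome(file.path(d, "genome.fa"))
  expect_identical(genome, sim$genome)
  ann <- read_annotation(file.path(d, "genes.gff3"))
  expect_equal(as.data.frame(ann), as.data.frame(sim$annotation))
  expr <- read_expression(file.path(d, "expr.tsv"))
  merged <- dplyr::inner_join(
    expr, sim$expr, by = c("gene_id", "strain", "condition", "replicate"))
  expect_equal(nrow(merged), nrow(sim$expr))
  expect_equal(merged$fpkm.x, merged$fpkm.y, tolerance = 1e-12)
  m <- read_matrix_tsv(file.path(d, "matrix.tsv"))
  expect_equal(m, sim$config$site_matrix$mat, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("config validation rejects impossible study designs", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, n_genes = 10, n_core = 8,
                                 n_sites_only = 2, n_affected_only = 2),
               class = "regulonscan_contract_error")
  expect_error(simulation_config(seed = 1, target_stringency_range = c(0.5, 1)),
               class = "regulonscan_contract_error")
  expect_error(simulation_config(seed = 1, annotated_fraction = 1.2),
               class = "regulonscan_contract_error")
})
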