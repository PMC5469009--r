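test_that("frequency matrix follows the additive-pseudocount formula", {
  fm0 <- build_frequency_matrix("ACGT", pseudocount_total = 0)
  expect_equal(unname(fm0$mat["A", 1]), 1)
  expect_equal(unname(fm0$mat["C", 1]), 0)
  expect_equal(unname(fm0$mat["G", 3]), 1)

  fm <- build_frequency_matrix(c("AA", "AC"), pseudocount_total = 1)
  expect_equal(unname(fm$mat["A", 2]), (1 + 0.25) / 3)
  expect_equal(unname(fm$mat["C", 2]), (1 + 0.25) / 3)
  expect_equal(unname(fm$mat["G", 2]), 0.25 / 3)
  expect_equal(unname(fm$mat["T", 2]), 0.25 / 3)
  expect_equal(colSums(fm$mat), rep(1, 2), ignore_attr = TRUE)

  # duplicated sites double counts but leave the frequencies unchanged
  fm1 <- build_frequency_matrix(c("ACGT", "ACGT"), pseudocount_total = 1)
  expect_equal(unname(fm1$mat["A", 1]), (2 + 0.25) / 3)
  expect_equal(colSums(fm1$mat), rep(1, 4), ignore_attr = TRUE)

  expect_error(build_frequency_matrix(c("AC", "ACG")),
               class = "regulonscan_contract_error")
  expect_error(build_frequency_matrix("ACNT"),
               class = "regulonscan_contract_error")
  expect_error(build_frequency_matrix(character(0)),
               class = "regulonscan_contract_error")
})

test_that("background frequencies count unambiguous bases only", {
  expect_equal(background_from_genome(c(c1 = "ACGT")),
               c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_equal(background_from_genome(c(c1 = "AACG")),
               c(A = 0.5, C = 0.25, G = 0.25, T = 0))
  b <- background_from_genome(c(c1 = "AAAN"))
  expect_equal(b[["A"]], 1)
  expect_error(background_from_genome(c(c1 = "NNNN")),
               class = "regulonscan_contract_error")
})

test_that("log-likelihood transform matches the closed form and rejects degenerate input", {
  fm <- frequency_matrix(matrix(c(0.85, 0.05, 0.05, 0.05), 4, 1,
                                dimnames = list(c("A", "C", "G", "T"), NULL)))
  sm <- log_likelihood_transform(fm, uniform_background)
  expect_equal(unname(sm$mat["A", 1]), log2(3.4), tolerance = 1e-12)
  expect_equal(sm$max_score, log2(3.4), tolerance = 1e-12)

  # matrix identical to background carries no information
  flat <- frequency_matrix(matrix(0.25, 4, 3,
                                  dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_error(log_likelihood_transform(flat, uniform_background),
               "uninformative", class = "regulonscan_uninformative_matrix")

  # zero background frequency is a background error
  expect_error(log_likelihood_transform(fm, c(A = 1, C = 0, G = 0, T = 0)),
               class = "regulonscan_background_error")
})

test_that("promoter extraction is strand-aware and truncates at contig bounds", {
  genome <- c(c1 = paste(rep("ACGTT", 1000), collapse = ""))  # 5 kb
  ann <- tibble::tibble(
    gene_id = c("gp", "gt", "gm"), contig = "c1",
    start = c(1000L, 300L, 1000L), end = c(2000L, 900L, 2000L),
    strand = c("+", "+", "-")
  )
  pr <- extract_promoters(genome, ann, 1000)
  expect_equal(pr$start[pr$gene_id == "gp"], 0L)
  expect_equal(pr$end[pr$gene_id == "gp"], 1000L)
  expect_equal(nchar(pr$sequence[pr$gene_id == "gp"]), 1000L)
  # truncation: only 300 bp upstream exist
  expect_equal(pr$start[pr$gene_id == "gt"], 0L)
  expect_equal(nchar(pr$sequence[pr$gene_id == "gt"]), 300L)
  # '-' gene: promoter is the reverse complement of the downstream interval
  expect_equal(pr$sequence[pr$gene_id == "gm"],
               oracle_revcomp(substr(genome[["c1"]], 2001, 3000)))

  expect_error(extract_promoters(genome,
                                 dplyr::mutate(ann, contig = "c9"), 1000),
               "unknown contig", class = "regulonscan_contract_error")
})

test_that("window scores agree with exhaustive table summation", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      L <- sample(2:8, 1)
      fm <- random_frequency_matrix(L)
      sm <- log_likelihood_transform(fm, uniform_background)
      w <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      expect_equal(score_window(sm, w), oracle_score(sm$mat, w),
                   tolerance = 1e-12)
    }
  })
  fm <- example_site_matrix()
  sm <- log_likelihood_transform(fm, uniform_background)
  expect_equal(score_window(sm, argmax_sequence(sm)), sm$max_score)
  argmin_seq <- paste(c("A", "C", "G", "T")[apply(sm$mat, 2, which.min)],
                      collapse = "")
  expect_equal(score_window(sm, argmin_seq), sm$min_score)
  expect_identical(score_window(sm, paste(rep("N", sm$width), collapse = "")),
                   -Inf)
  expect_error(score_window(sm, "ACGT"), class = "regulonscan_contract_error")
})

test_that("scan recovers a planted consensus site with its palindromic mirror", {
  sm <- log_likelihood_transform(example_site_matrix(), uniform_background)
  withr::with_seed(9, {
    prom <- random_promoter_record(400)
  })
  prom$strand <- "+"
  planted <- plant_site(prom$sequence, sm, 1.0, "+", 150)
  prom$sequence <- planted$sequence
  sites <- scan_promoter(sm, prom, scan_config(stringency_threshold = 0.6))
  planted_hits <- sites[sites$start == prom$start + 150, ]
  expect_gte(nrow(planted_hits), 1)
  expect_equal(max(planted_hits$stringency), 1.0)
  # the example matrix is exactly self-reverse-complementary: the planted
  # interval is hit on both strands but counts as one site
  expect_setequal(planted_hits$strand, c("+", "-"))
  expect_equal(site_count(planted_hits), 1L)

  prom$sequence <- paste(rep("N", 400), collapse = "")
  expect_equal(nrow(scan_promoter(sm, prom)), 0)
})

test_that("promoters shorter than the motif yield no sites", {
  sm <- log_likelihood_transform(example_site_matrix(), uniform_background)
  short <- list(gene_id = "g", contig = "c1", start = 0L, end = 5L,
                strand = "+", sequence = "ACGTA")
  expect_equal(nrow(scan_promoter(sm, short)), 0)
})

test_that("site_count deduplicates palindromic strand pairs and rejects mixed genes", {
  sites <- tibble::tibble(
    gene_id = "g1", contig = "c1",
    start = c(10L, 10L, 40L, 70L), end = c(29L, 29L, 59L, 89L),
    strand = c("+", "-", "+", "+"), score = 1, stringency = 0.9
  )
  expect_equal(site_count(sites), 3L)
  expect_equal(site_count(sites[0, ]), 0L)
  expect_error(site_count(dplyr::mutate(sites, gene_id = c("g1", "g2", "g1", "g1"))),
               class = "regulonscan_contract_error")
  counts <- site_counts(sites)
  expect_equal(counts$n_sites, 3L)
})

test_that("stringency never exceeds 1 and argmax scores exactly 1", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      L <- sample(3:10, 1)
      sm <- log_likelihood_transform(random_frequency_matrix(L),
                                     uniform_background)
      expect_equal(score_window(sm, argmax_sequence(sm)) / sm$max_score, 1)
      prom <- random_promoter_record(300)
      sites <- scan_promoter(sm, prom, scan_config(stringency_threshold = 0.01))
      if (nrow(sites) > 0) expect_true(all(sites$stringency <= 1 + 1e-12))
    }
  })
})

test_that("substituting a column argmax base never decreases a window score", {
  withr::with_seed(33, {
    sm <- log_likelihood_transform(random_frequency_matrix(6),
                                   uniform_background)
    best <- strsplit(argmax_sequence(sm), NULL)[[1]]
    for (rep in 1:30) {
      w <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
      j <- sample(6, 1)
      w2 <- w
      w2[j] <- best[j]
      expect_gte(score_window(sm, paste(w2, collapse = "")),
                 score_window(sm, paste(w, collapse = "")))
    }
  })
})

test_that("scanning the reverse-complemented promoter mirrors the site list", {
  withr::with_seed(14, {
    sm <- log_likelihood_transform(random_frequency_matrix(5),
                                   uniform_background)
    prom <- random_promoter_record(500)
    prom$strand <- "+"
    fwd <- scan_promoter(sm, prom, scan_config(stringency_threshold = 0.3))
    # the same physical DNA handed over as the promoter of a '-' gene with
    # mirrored coordinates must give the same genomic site list
    mirrored <- list(gene_id = "g1", contig = "c1",
                     start = prom$start, end = prom$end, strand = "-",
                     sequence = oracle_revcomp(prom$sequence))
    rev <- scan_promoter(sm, mirrored, scan_config(stringency_threshold = 0.3))
    expect_equal(fwd$start, rev$start)
    expect_equal(fwd$strand, rev$strand)
    expect_equal(fwd$score, rev$score, tolerance = 1e-12)
  })
})

test_that("genes_with_sites returns exactly the motif-bearing genes", {
  sites <- tibble::tibble(
    gene_id = c("g2", "g1", "g2"), contig = "c1",
    start = c(1L, 5L, 30L), end = c(20L, 24L, 49L),
    strand = "+", score = 1, stringency = 0.8
  )
  expect_equal(genes_with_sites(sites), c("g1", "g2"))
  expect_equal(genes_with_sites(sites[0, ]), character(0))
})

test_that("BED output is byte-identical across repeated scans", {
  sim <- simulate_genome(simulation_config(seed = 3, n_genes = 8, n_core = 3,
                                           n_sites_only = 2,
                                           n_affected_only = 2))
  cfg <- scan_config()
  s1 <- scan_genome(sim$genome, sim$annotation, sim$scoring_matrix, cfg)
  s2 <- scan_genome(sim$genome, sim$annotation, sim$scoring_matrix, cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_sites_bed(s1, f1)
  write_sites_bed(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(nrow(s1), 0)
})
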