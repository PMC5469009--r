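# Independent brute-force oracles. These deliberately re-derive results from
# first principles (loops, choose() arithmetic, naive agglomeration) and share
# no code with the implementation paths they check.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), NULL)[[1]]), collapse = "")
}

oracle_score <- function(P, window) {
  chars <- strsplit(window, NULL)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(idx)) return(-Inf)
  s <- 0
  for (j in seq_along(idx)) s <- s + unname(P[idx[j], j])
  s
}

# score all windows of a promoter record on both strands, apply the strict
# stringency threshold, and map to genomic forward-strand coordinates
oracle_scan <- function(sm, promoter, threshold = 0.6, both_strands = TRUE) {
  L <- ncol(sm$mat)
  seq <- promoter$sequence
  n <- nchar(seq) - L + 1
  rows <- list()
  if (n >= 1) {
    for (i in seq_len(n)) {
      win <- substr(seq, i, i + L - 1)
      strands <- if (both_strands) c("+", "-") else "+"
      for (ps in strands) {
        w <- if (ps == "+") win else oracle_revcomp(win)
        sc <- oracle_score(sm$mat, w)
        if (is.finite(sc) && sc / sm$max_score > threshold) {
          if (promoter$strand == "+") {
            gstart <- promoter$start + (i - 1)
            gstrand <- ps
          } else {
            gstart <- promoter$end - (i - 1) - L
            gstrand <- if (ps == "+") "-" else "+"
          }
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = promoter$gene_id, contig = promoter$contig,
            start = gstart, end = gstart + L, strand = gstrand,
            score = sc, stringency = sc / sm$max_score
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      score = numeric(), stringency = numeric())
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

oracle_hyper_pmf <- function(i, n, K, N) {
  choose(K, i) * choose(N - K, n - i) / choose(N, n)
}

oracle_hyper_tail <- function(k, n, K, N) {
  if (k <= 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(vapply(k:hi, oracle_hyper_pmf, numeric(1), n = n, K = K, N = N))
}

# naive average-linkage agglomeration stopping at a height cut; returns the
# partition as an integer vector over rownames(d)
oracle_average_linkage_cut <- function(dmat, h) {
  clusters <- as.list(seq_len(nrow(dmat)))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        d_ab <- mean(dmat[clusters[[a]], clusters[[b]]])
        if (d_ab < best_d) {
          best_d <- d_ab
          best <- c(a, b)
        }
      }
    }
    if (best_d > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(nrow(dmat))
  for (i in seq_along(clusters)) out[clusters[[i]]] <- i
  names(out) <- rownames(dmat)
  out
}

# partitions agree up to label permutation
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

oracle_venn <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  sig <- vapply(universe, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  split(universe, sig)
}

random_frequency_matrix <- function(L) {
  m <- matrix(stats::runif(4 * L, 0.02, 1), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  frequency_matrix(sweep(m, 2, colSums(m), "/"))
}

random_promoter_record <- function(len, gene = "g1") {
  list(gene_id = gene, contig = "c1",
       start = 5000L, end = 5000L + len,
       strand = sample(c("+", "-"), 1),
       sequence = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""))
}

uniform_background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
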