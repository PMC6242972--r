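se_call <- function(sample_id, start, end, signal = 1, chrom = "chr17") {
  tibble::tibble(sample_id = sample_id, chrom = chrom, start = start,
                 end = end, signal = signal)
}

test_that("clustering merges by gap and respects transitivity", {
  one <- cluster_se_calls(se_call("A", 100, 200), max_gap = 500)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(100, 200))
  expect_equal(one$recurrence, 1L)

  calls <- dplyr::bind_rows(se_call("A", 100, 200), se_call("B", 650, 900),
                            se_call("C", 1500, 1600))
  cl <- cluster_se_calls(calls, max_gap = 500)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$start, c(100, 1500))
  expect_equal(cl$end, c(900, 1600))
  expect_equal(cl$recurrence, c(2L, 1L))

  # chain: outer pair 950 apart but linked through the middle interval
  chain <- dplyr::bind_rows(se_call("A", 0, 100), se_call("A", 550, 600),
                            se_call("A", 1050, 1100))
  cl <- cluster_se_calls(chain, max_gap = 500)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start, cl$end), c(0, 1100))

  # different chromosomes never merge
  two_chrom <- dplyr::bind_rows(se_call("A", 0, 100, chrom = "chr1"),
                                se_call("A", 0, 100, chrom = "chr2"))
  expect_equal(nrow(cluster_se_calls(two_chrom, max_gap = 1e9)), 2)
})

test_that("clustering equals the O(n^2) transitive closure on random instances", {
  withr::with_seed(421, {
    for (rep in 1:200) {
      n <- sample(2:60, 1)
      start <- sample.int(5000, n, replace = TRUE)
      width <- sample.int(300, n, replace = TRUE)
      gap <- sample(c(0, 10, 100, 500), 1)
      calls <- tibble::tibble(sample_id = sprintf("c%03d", seq_len(n)),
                              chrom = "chr1", start = start,
                              end = start + width, signal = 1)
      cl <- cluster_se_calls(calls, max_gap = gap)
      got <- canonical_partition(
        rep(seq_len(nrow(cl)), vapply(cl$members, nrow, integer(1))),
        unlist(lapply(cl$members, `[[`, "sample_id")))
      comp <- closure_components(start, start + width, gap)
      expect_identical(got, canonical_partition(comp, calls$sample_id))
    }
  })
})

test_that("cluster counts are monotone in max_gap and calls are conserved", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- 40
      start <- sample.int(20000, n, replace = TRUE)
      calls <- tibble::tibble(sample_id = sprintf("s%d", seq_len(n)),
                              chrom = "chr1", start = start,
                              end = start + sample.int(200, n, TRUE),
                              signal = runif(n))
      sizes <- vapply(c(0, 50, 200, 1000, 5000), function(g) {
        cl <- cluster_se_calls(calls, max_gap = g)
        # every input call lands in exactly one cluster
        expect_equal(sum(vapply(cl$members, nrow, integer(1))), n)
        nrow(cl)
      }, integer(1))
      expect_true(all(diff(sizes) <= 0))
    }
  })
})

test_that("median rank, ordering and recurrence filtering follow the rules", {
  # ranks {3,10,20} vs {1,2}: median ranks 10 and 1.5
  calls <- dplyr::bind_rows(
    tibble::tibble(sample_id = c("A", "B", "C"), chrom = "chr1",
                   start = 1000, end = 2000, rank = c(3L, 10L, 20L)),
    tibble::tibble(sample_id = c("A", "B"), chrom = "chr1",
                   start = 10000, end = 11000, rank = c(1L, 2L))
  )
  cl <- cluster_se_calls(calls, max_gap = 500)
  expect_equal(sort(cl$median_rank), c(1.5, 10))
  ranked <- rank_and_filter_clusters(cl, top_n = 500, min_recurrence = 1)
  expect_equal(ranked$median_rank, c(1.5, 10))

  # recurrence bound is inclusive ("min 20")
  cl2 <- tibble::tibble(cluster_id = c("x", "y", "z"), chrom = "chr1",
                        start = c(1, 2, 3), end = c(10, 11, 12),
                        recurrence = c(26L, 19L, 20L),
                        median_rank = c(1, 2, 3), members = list(NULL))
  kept <- rank_and_filter_clusters(cl2, top_n = 500, min_recurrence = 20)
  expect_setequal(kept$recurrence, c(26L, 20L))

  # equal median ranks: higher recurrence wins the top_n cut
  cl3 <- tibble::tibble(cluster_id = c("a", "b"), chrom = "chr1",
                        start = c(100, 1), end = c(110, 11),
                        recurrence = c(5L, 9L), median_rank = c(2, 2),
                        members = list(NULL))
  expect_equal(rank_and_filter_clusters(cl3, top_n = 1,
                                        min_recurrence = 1)$cluster_id, "b")
})

test_that("within-sample ranks come from descending signal when absent", {
  calls <- tibble::tibble(sample_id = "A", chrom = "chr1",
                          start = c(10, 500, 900),
                          end = c(20, 510, 910),
                          signal = c(5, 9, 9))
  ranked <- rank_se_calls(calls)
  # ties by leftmost start: the two signal-9 calls rank 1 then 2
  expect_equal(ranked$rank[order(ranked$start)], c(3L, 1L, 2L))
  dup <- tibble::tibble(sample_id = "A", chrom = "chr1", start = c(1, 5),
                        end = c(2, 6), rank = c(1L, 1L))
  expect_error(rank_se_calls(dup), "duplicate within-sample rank")
})

test_that("gene annotation uses inclusive TSS distance to the cluster span", {
  cl <- tibble::tibble(cluster_id = "c1", chrom = "chr1", start = 1e6,
                       end = 1.01e6, recurrence = 3L, median_rank = 1,
                       members = list(tibble::tibble(sample_id = c("A", "B", "C"))))
  gene_at <- function(tss) {
    tibble::tibble(gene_id = "g", symbol = "g", chrom = "chr1", tss = tss,
                   is_tf = TRUE)
  }
  expect_equal(nrow(annotate_candidate_genes(cl, gene_at(1510000), 5e5)), 1)
  expect_equal(nrow(annotate_candidate_genes(cl, gene_at(1005000), 5e5)), 1)
  expect_equal(nrow(annotate_candidate_genes(cl, gene_at(1510001), 5e5)), 0)
  expect_equal(nrow(annotate_candidate_genes(cl, gene_at(500000), 5e5)), 1)
  expect_equal(nrow(annotate_candidate_genes(cl, gene_at(499999), 5e5)), 0)

  # strand-aware TSS derivation: gene body [1.4 Mb, 2.2 Mb) is within
  # reach only through its plus-strand TSS (start); the minus-strand TSS
  # (end - 1) lies ~1.19 Mb from the cluster
  g <- tibble::tibble(gene_id = "g", symbol = "g", chrom = "chr1",
                      start = 1.4e6, end = 2.2e6, strand = "-", is_tf = TRUE)
  expect_equal(nrow(annotate_candidate_genes(cl, g, 5e5)), 0)
  g$strand <- "+"
  expect_equal(nrow(annotate_candidate_genes(cl, g, 5e5)), 1)
})

test_that("active-TSS filter requires a peak in every harboring sample", {
  cand <- tibble::tibble(
    gene_id = c("tf_ok", "tf_gap", "not_tf"), symbol = c("a", "b", "c"),
    chrom = "chr1", tss = c(1000, 1000, 1000),
    is_tf = c(TRUE, TRUE, FALSE),
    cluster_ids = list("c1", "c1", "c1"), n_clusters = 1L,
    harboring_samples = list(c("A", "B", "C"), c("A", "B", "C"),
                             c("A", "B", "C"))
  )
  peak <- tibble::tibble(chrom = "chr1", start = 500, end = 1200)
  none <- tibble::tibble(chrom = "chr1", start = 5e4, end = 5.1e4)
  peaks_all <- list(A = peak, B = peak, C = peak)
  kept <- filter_active_tfs(cand[c(1, 3), ], peaks_all)
  expect_equal(kept$gene_id, "tf_ok")  # non-TF excluded despite peaks

  peaks_gap <- list(A = peak, B = peak, C = none)
  expect_equal(nrow(filter_active_tfs(cand[2, ], peaks_gap)), 0)

  # union semantics across two clusters: only member samples are checked
  multi <- cand[1, ]
  multi$cluster_ids <- list(c("c1", "c2"))
  multi$harboring_samples <- list(c("A", "B"))
  kept <- filter_active_tfs(multi, list(A = peak, B = peak))
  expect_equal(nrow(kept), 1)

  # harboring sample missing from the peak map is a loud error
  expect_error(filter_active_tfs(cand[1, ], list(A = peak, B = peak)),
               "sample 'C'")
})

test_that("run_prioritization recovers the planted driver and is deterministic", {
  land <- simulate_se_landscape(seed = 11)
  coh <- simulate_cohort(seed = 12)
  cfg <- prioritization_config(
    region = tibble::tibble(chrom = "chr17", start = 38.1e6, end = 81e6))
  rep1 <- run_prioritization(land$se_calls, land$genes, coh$expression,
                             coh$survival, coh$segments, coh$stage,
                             land$tss_peaks, config = cfg)
  expect_equal(rep1$gene_id[1], land$truth$driver_gene)
  expect_true(all(rep1$is_tf))
  expect_lt(rep1$survival_p[1], 1e-4)
  expect_lt(rep1$dosage_p[1], 0.01)
  expect_equal(rep1$survival_padj,
               p.adjust(rep1$survival_p, method = "BH"))

  rep2 <- run_prioritization(land$se_calls, land$genes, coh$expression,
                             coh$survival, coh$segments, coh$stage,
                             land$tss_peaks, config = cfg)
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))

  # empty SE input gives an empty report, no error
  empty <- run_prioritization(land$se_calls[0, ], land$genes,
                              coh$expression, coh$survival,
                              config = cfg)
  expect_equal(nrow(empty), 0)
})

test_that("candidates without expression sort last with NA survival p", {
  land <- simulate_se_landscape(seed = 31)
  coh <- simulate_cohort(seed = 32)
  expr <- coh$expression[coh$expression$gene_id != land$truth$driver_gene, ]
  cfg <- prioritization_config(
    region = tibble::tibble(chrom = "chr17", start = 38.1e6, end = 81e6))
  rep <- run_prioritization(land$se_calls, land$genes, expr, coh$survival,
                            tss_peaks = land$tss_peaks, config = cfg)
  driver_row <- which(rep$gene_id == land$truth$driver_gene)
  expect_true(is.na(rep$survival_p[driver_row]))
  expect_equal(driver_row, nrow(rep))
})
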