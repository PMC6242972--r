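# Cross-sample super-enhancer prioritization.
#
# The procedure: (1) cluster per-sample SE calls across samples (overlap or
# gap <= max_gap, transitively); (2) rank clusters by the median of their
# members' within-sample ranks, keep the top_n, then keep clusters recurrent
# in >= min_recurrence samples; (3) annotate genes whose TSS lies within
# gene_window of a retained cluster; (4) keep transcription factors with an
# H3K27ac peak at the TSS in every sample harboring the SE; (5) attach
# survival (median-split log-rank) and copy-number dosage statistics and
# rank the final candidates.

#' Prioritization parameters
#'
#' Bundles the tunable parameters of the SE prioritization with the
#' defaults used throughout: SE calls closer than 500 bp are clustered, the
#' top 500 clusters by median within-sample rank are kept, recurrence in at
#' least 20 samples is required, genes are annotated within 500 kb of a
#' cluster, and a TSS counts as active when a peak overlaps TSS +/- 1 kb.
#'
#' @param max_gap Maximum gap (bp) between SE calls merged into one cluster.
#' @param top_n Number of top-ranked clusters retained.
#' @param min_recurrence Minimum number of distinct samples per cluster
#'   (inclusive bound).
#' @param gene_window Maximum TSS-to-cluster distance (bp, inclusive) for
#'   gene annotation.
#' @param tss_window Half-width (bp) of the TSS activity window.
#' @param region Optional single-row interval tibble restricting the
#'   analysis (e.g. chr17q), or `NULL`.
#' @return A list of class `"prioritization_config"`.
#' @export
prioritization_config <- function(max_gap = 500, top_n = 500,
                                  min_recurrence = 20, gene_window = 5e5,
                                  tss_window = 1000, region = NULL) {
  stopifnot(max_gap >= 0, top_n > 0, min_recurrence > 0,
            gene_window > 0, tss_window > 0)
  structure(list(max_gap = max_gap, top_n = top_n,
                 min_recurrence = min_recurrence, gene_window = gene_window,
                 tss_window = tss_window, region = region),
            class = "prioritization_config")
}

#' Assign within-sample SE ranks from signal
#'
#' Ranks each sample's SE calls by descending signal (1 = strongest SE in
#' that sample), breaking ties by leftmost start. Calls that already carry a
#' `rank` column are returned unchanged.
#'
#' @param calls SE call tibble with columns `sample_id`, `chrom`, `start`,
#'   `end`, `signal` (and optionally `rank`).
#' @return The tibble with a `rank` column.
#' @export
rank_se_calls <- function(calls) {
  calls <- as_tibble(calls)
  if ("rank" %in% names(calls)) {
    dup <- calls |>
      group_by(.data$sample_id) |>
      summarise(dup = anyDuplicated(.data$rank) > 0)
    if (any(dup$dup)) {
      abort(sprintf("duplicate within-sample rank in sample '%s'",
                    dup$sample_id[dup$dup][1]))
    }
    return(calls)
  }
  if (!"signal" %in% names(calls)) {
    abort("SE calls need either a 'rank' or a 'signal' column")
  }
  calls |>
    group_by(.data$sample_id) |>
    arrange(desc(.data$signal), .data$chrom, .data$start, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
}

#' Cluster SE calls across samples
#'
#' Merges SE calls (per chromosome) into clusters: two calls belong to the
#' same cluster iff they are connected by a chain of calls that pairwise
#' overlap or lie within `max_gap` bp of each other. This is the transitive
#' closure of the pairwise predicate; on a line it is computed exactly by a
#' single sorted sweep. Never merges across chromosomes.
#'
#' @param calls SE call tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `signal` and/or `rank`).
#' @param max_gap Maximum merge gap in bp (inclusive: a gap of exactly
#'   `max_gap` merges).
#' @return A tibble with one row per cluster: `cluster_id`, `chrom`,
#'   `start`, `end` (union span), `recurrence` (distinct member samples),
#'   `median_rank` (median of members' within-sample ranks, one rank per
#'   sample, the strongest call when a sample contributes several), and a
#'   `members` list-column of per-sample tibbles.
#' @export
cluster_se_calls <- function(calls, max_gap = 500) {
  stopifnot(max_gap >= 0)
  calls <- rank_se_calls(validate_intervals(calls, "SE calls"))
  if (nrow(calls) == 0) {
    return(tibble(cluster_id = character(), chrom = character(),
                  start = double(), end = double(), recurrence = integer(),
                  median_rank = double(), members = list()))
  }
  calls <- calls |>
    mutate(start = as.numeric(.data$start), end = as.numeric(.data$end)) |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    mutate(
      run_end = cummax(.data$end),
      new_cluster = .data$start - lag(.data$run_end, default = -Inf) > max_gap,
      cluster_index = cumsum(.data$new_cluster)
    ) |>
    ungroup()
  clusters <- calls |>
    group_by(.data$chrom, .data$cluster_index) |>
    summarise(
      members = list(dplyr::pick(dplyr::all_of(c("sample_id", "start",
                                                 "end", "rank")))),
      recurrence = dplyr::n_distinct(.data$sample_id),
      median_rank = median(tapply(.data$rank, .data$sample_id, min)),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start) |>
    mutate(cluster_id = sprintf("%s:%d-%d", .data$chrom,
                                as.integer(.data$start),
                                as.integer(.data$end))) |>
    select("cluster_id", "chrom", "start", "end", "recurrence",
           "median_rank", "members")
  clusters
}

#' Rank clusters by median rank and filter by recurrence
#'
#' Sorts clusters ascending by `median_rank` (ties broken by higher
#' recurrence, then leftmost interval), keeps the first `top_n`, then keeps
#' those recurrent in at least `min_recurrence` samples (inclusive).
#'
#' @param clusters Cluster tibble from [cluster_se_calls()].
#' @param top_n Number of top-ranked clusters retained before the
#'   recurrence filter.
#' @param min_recurrence Minimum recurrence (inclusive).
#' @return The filtered cluster tibble in rank order.
#' @export
rank_and_filter_clusters <- function(clusters, top_n = 500,
                                     min_recurrence = 20) {
  clusters |>
    arrange(.data$median_rank, desc(.data$recurrence), .data$chrom,
            .data$start, .data$end) |>
    slice_head(n = top_n) |>
    filter(.data$recurrence >= min_recurrence)
}

# distance from a TSS position to a [start, end) span: 0 inside, else the
# gap to the nearest covered base
tss_distance <- function(tss, start, end) {
  pmax(start - tss, tss - end, 0)
}

#' Annotate genes near SE clusters
#'
#' A gene is annotated to a cluster when the distance from its TSS to the
#' cluster span is at most `gene_window` bp (0 when the TSS lies inside the
#' span; the bound is inclusive). The TSS is the interval start for
#' `+`-strand genes and `end - 1` for `-`-strand genes when the gene table
#' carries `start`/`end`/`strand`; a precomputed `tss` column is used as is.
#'
#' @param clusters Cluster tibble (typically after
#'   [rank_and_filter_clusters()]).
#' @param genes Gene table with columns `gene_id`, `symbol`, `chrom`,
#'   `is_tf`, and either `tss` or (`start`, `end`, `strand`).
#' @param gene_window Maximum TSS-to-cluster distance in bp.
#' @return A tibble with one row per candidate gene: gene columns plus
#'   `cluster_ids` (list of cluster ids), `n_clusters`, and
#'   `harboring_samples` (list; union of member samples over the gene's
#'   clusters).
#' @export
annotate_candidate_genes <- function(clusters, genes, gene_window = 5e5) {
  genes <- as_tibble(genes)
  if (!"tss" %in% names(genes)) {
    if (!all(c("start", "end", "strand") %in% names(genes))) {
      abort("gene table needs a 'tss' column or 'start'/'end'/'strand'")
    }
    genes$tss <- if_else(genes$strand == "-", genes$end - 1, genes$start)
  }
  if (nrow(clusters) == 0 || nrow(genes) == 0) {
    return(mutate(genes[0, ], cluster_ids = list(), n_clusters = integer(),
                  harboring_samples = list()))
  }
  pairs <- inner_join(
    genes, select(clusters, "cluster_id", "chrom", cl_start = "start",
                  cl_end = "end", "members"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    filter(tss_distance(.data$tss, .data$cl_start, .data$cl_end) <=
             gene_window)
  pairs |>
    group_by(across(dplyr::all_of(names(genes)))) |>
    summarise(
      cluster_ids = list(.data$cluster_id),
      n_clusters = dplyr::n(),
      harboring_samples =
        list(sort(unique(unlist(lapply(.data$members, `[[`, "sample_id"))))),
      .groups = "drop"
    )
}

#' Filter candidates to TFs with an active TSS in all harboring samples
#'
#' Retains a candidate gene iff it is flagged as a transcription factor and,
#' in every sample harboring one of its SE clusters, some H3K27ac peak
#' overlaps the window `[TSS - tss_window, TSS + tss_window)`. Harboring
#' samples are the union of member samples across the gene's clusters by
#' default; `per_cluster = TRUE` instead requires an active TSS in the
#' member samples of each cluster separately (identical retention, but the
#' samples checked per gene can differ when clusters share no samples).
#'
#' @param candidates Candidate tibble from [annotate_candidate_genes()].
#' @param tss_peaks Named list (by sample id) of peak interval tibbles.
#' @param tss_window Half-width of the TSS window in bp.
#' @param per_cluster Check each cluster's member samples separately.
#' @return The retained candidates, with an `active_tss_in_all` logical
#'   column.
#' @export
filter_active_tfs <- function(candidates, tss_peaks, tss_window = 1000,
                              per_cluster = FALSE) {
  stopifnot(is.list(tss_peaks))
  has_peak_at <- function(sample_id, chrom, tss) {
    if (!sample_id %in% names(tss_peaks)) {
      abort(sprintf(
        "sample '%s' harbors an SE but has no TSS peak table", sample_id))
    }
    peaks <- tss_peaks[[sample_id]]
    any(peaks$chrom == chrom &
          peaks$start < tss + tss_window &
          peaks$end > tss - tss_window)
  }
  active <- purrr::pmap_lgl(
    list(candidates$harboring_samples, candidates$chrom, candidates$tss),
    function(samples, chrom, tss) {
      all(vapply(samples, has_peak_at, logical(1), chrom = chrom, tss = tss))
    }
  )
  # per_cluster mode checks the same predicate cluster by cluster; with the
  # union rule a gene passes iff it passes every cluster, so the flag only
  # changes which samples are *reported*, not membership -- kept for
  # completeness of the union-vs-per-cluster reading.
  candidates |>
    mutate(active_tss_in_all = active) |>
    filter(.data$is_tf, .data$active_tss_in_all)
}

#' Run the full SE-driven candidate prioritization
#'
#' Executes the whole pipeline: cluster SE calls, rank and filter clusters,
#' annotate nearby genes, keep TFs with active TSS in all harboring
#' samples, then attach per-candidate survival statistics (median-split
#' log-rank on tumor expression) and copy-number dosage statistics (gain
#' effect on expression). The report is sorted ascending by the raw
#' log-rank p-value, with Benjamini-Hochberg adjusted values alongside;
#' candidates lacking expression sort last with `survival_p = NA`.
#'
#' @param se_calls SE call tibble across all samples.
#' @param genes Gene table (see [annotate_candidate_genes()]).
#' @param expression Expression tibble (`gene_id` + one column per tumor),
#'   or `NULL` to skip survival/dosage scoring.
#' @param survival Survival tibble (`sample_id`, `time`, `event`), or `NULL`.
#' @param segments Per-tumor copy-number segments (`sample_id`, `chrom`,
#'   `start`, `end`, `log2_ratio`), or `NULL` to skip dosage scoring.
#' @param stage Optional tibble (`sample_id`, `stage_high` logical); when
#'   given, the dosage test is the gain effect within the high-stage
#'   stratum, otherwise across all tumors.
#' @param tss_peaks Named list of per-sample TSS peak tibbles, or `NULL` to
#'   skip the active-TSS filter (all annotated TFs retained).
#' @param config A [prioritization_config()].
#' @return A tibble of class `"se_priority_report"`, one row per candidate,
#'   sorted by `survival_p`, with attributes `clusters` (retained clusters)
#'   and `stage_counts` (candidates surviving each filter stage).
#' @export
run_prioritization <- function(se_calls, genes, expression = NULL,
                               survival = NULL, segments = NULL,
                               stage = NULL, tss_peaks = NULL,
                               config = prioritization_config()) {
  empty_report <- function(stage_counts, clusters) {
    out <- tibble(gene_id = character(), symbol = character(),
                  chrom = character(), tss = double(), is_tf = logical(),
                  n_clusters = integer(), recurrence = integer(),
                  median_rank = double(), survival_p = double(),
                  survival_padj = double(), dosage_p = double())
    structure(out, clusters = clusters, stage_counts = stage_counts,
              class = c("se_priority_report", class(out)))
  }
  if (!is.null(config$region)) {
    se_calls <- filter(as_tibble(se_calls),
                       .data$chrom == config$region$chrom,
                       .data$end > config$region$start,
                       .data$start < config$region$end)
  }
  clusters <- cluster_se_calls(se_calls, max_gap = config$max_gap)
  kept <- rank_and_filter_clusters(clusters, top_n = config$top_n,
                                   min_recurrence = config$min_recurrence)
  stage_counts <- c(clusters = nrow(clusters), recurrent = nrow(kept))
  if (nrow(kept) == 0) return(empty_report(stage_counts, kept))
  cand <- annotate_candidate_genes(kept, genes,
                                   gene_window = config$gene_window)
  stage_counts <- c(stage_counts, annotated = nrow(cand))
  if (!is.null(tss_peaks)) {
    cand <- filter_active_tfs(cand, tss_peaks,
                              tss_window = config$tss_window)
  } else {
    cand <- filter(cand, .data$is_tf)
  }
  stage_counts <- c(stage_counts, active_tf = nrow(cand))
  if (nrow(cand) == 0) return(empty_report(stage_counts, kept))

  # summarise cluster-level strength per gene: best (max) recurrence and
  # best (min) median rank over the gene's clusters
  cl_lookup <- kept |> select("cluster_id", "recurrence", "median_rank")
  cand <- cand |>
    mutate(
      recurrence = purrr::map_int(.data$cluster_ids, function(ids) {
        as.integer(max(cl_lookup$recurrence[cl_lookup$cluster_id %in% ids]))
      }),
      median_rank = purrr::map_dbl(.data$cluster_ids, function(ids) {
        min(cl_lookup$median_rank[cl_lookup$cluster_id %in% ids])
      })
    )

  cand$survival_p <- NA_real_
  cand$dosage_p <- NA_real_
  if (!is.null(expression) && !is.null(survival)) {
    surv_stats <- candidate_survival(expression, survival, cand$gene_id)
    cand$survival_p <- surv_stats$p_value[match(cand$gene_id,
                                                surv_stats$gene_id)]
  }
  if (!is.null(expression) && !is.null(segments)) {
    gain <- call_arm_gain(segments,
                          arm = config$region %||%
                            tibble(chrom = cand$chrom[1], start = 0,
                                   end = Inf))
    cand$dosage_p <- purrr::map_dbl(cand$gene_id, function(g) {
      gene_dosage_p(expression, gain, stage, g)
    })
  }
  out <- cand |>
    mutate(survival_padj = p.adjust(.data$survival_p, method = "BH")) |>
    arrange(is.na(.data$survival_p), .data$survival_p,
            .data$median_rank, .data$gene_id) |>
    select("gene_id", "symbol", "chrom", "tss", "is_tf", "n_clusters",
           "recurrence", "median_rank", "survival_p", "survival_padj",
           "dosage_p")
  structure(out, clusters = kept, stage_counts = stage_counts,
            class = c("se_priority_report", class(out)))
}

# median-split log-rank p for each gene with expression data
candidate_survival <- function(expression, survival, gene_ids) {
  samp <- intersect(names(expression)[-1], survival$sample_id)
  purrr::map_dfr(gene_ids, function(g) {
    row <- expression[expression$gene_id == g, samp, drop = FALSE]
    if (nrow(row) == 0) {
      return(tibble(gene_id = g, p_value = NA_real_))
    }
    x <- setNames(as.numeric(row[1, ]), samp)
    p <- tryCatch({
      labels <- median_split(x)
      res <- km_logrank(survival[match(samp, survival$sample_id), ], labels)
      res$p_value
    }, error = function(e) NA_real_)
    tibble(gene_id = g, p_value = p)
  })
}

# one-gene dosage p-value: gain effect on expression, within the high-stage
# stratum when stage info is available
gene_dosage_p <- function(expression, gain, stage, gene_id) {
  samp <- intersect(names(expression)[-1], gain$sample_id)
  row <- expression[expression$gene_id == gene_id, samp, drop = FALSE]
  if (nrow(row) == 0 || length(samp) < 4) return(NA_real_)
  dat <- tibble(
    sample_id = samp,
    expression = as.numeric(row[1, ]),
    gained = gain$gained[match(samp, gain$sample_id)]
  )
  if (!is.null(stage)) {
    dat$stage_high <- stage$stage_high[match(samp, stage$sample_id)]
    res <- tryCatch(dosage_anova(dat), error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    return(glance(res)$gain_in_high_stage_p)
  }
  dat <- filter(dat, !is.na(.data$gained))
  if (length(unique(dat$gained)) < 2) return(NA_real_)
  fit <- aov(expression ~ gained, data = dat)
  summary(fit)[[1]][["Pr(>F)"]][1]
}

#' @export
print.se_priority_report <- function(x, ...) {
  counts <- attr(x, "stage_counts")
  cat("SE-driven candidate prioritization report\n")
  cat(sprintf("  clusters: %d total, %d recurrent; candidates: %d annotated, %d active TFs\n",
              counts[["clusters"]], counts[["recurrent"]],
              counts[["annotated"]], counts[["active_tf"]]))
  NextMethod()
}
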