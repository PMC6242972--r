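# Seeded generators for every input class the pipeline consumes. Each
# generator is a pure function of its parameters and seed (same seed, same
# output) and returns a `truth` record sufficient to score recovery.
#
# The default parameters emulate the study conditions the pipeline was
# designed for: 26 cell-line samples on a gained 17q arm with the planted
# driver SE present in 24 of them, tumor cohorts of a few hundred cases
# with expression linked to survival hazard and to copy-number gain, 4C
# tracks with sparse Bernoulli background coverage, and three-fold dilution
# checkerboards built from Hill response curves under Bliss independence.

#' Simulate a cross-sample super-enhancer landscape
#'
#' Plants one driver SE cluster (present in `harboring_samples` samples,
#' always the strongest SE of its sample) and `n_decoy_clusters` decoy
#' clusters with weaker signals and variable recurrence, spaced far enough
#' apart (1 Mb) that clustering at the default 500 bp gap recovers exactly
#' the planted clusters. Also emits a matching gene table (a driver TF at
#' the driver cluster, decoy TFs and non-TF genes at the decoys) and
#' per-sample H3K27ac TSS peak tables in which the driver TSS is active in
#' every sample.
#'
#' @param n_samples Number of cell-line samples.
#' @param n_decoy_clusters Number of decoy SE clusters.
#' @param harboring_samples Samples harboring the driver SE.
#' @param min_decoy_recurrence,max_decoy_recurrence Range the decoy
#'   recurrences are drawn from.
#' @param chrom Chromosome name.
#' @param region_start Leftmost coordinate of the simulated arm (bp).
#' @param cluster_spacing Distance between planted cluster anchors (bp).
#' @param seed Integer seed (mandatory).
#' @return A list: `se_calls` (tibble across samples), `genes`,
#'   `tss_peaks` (named list per sample), and `truth` (planted spans,
#'   recurrences, driver gene/cluster ids).
#' @export
simulate_se_landscape <- function(n_samples = 26, n_decoy_clusters = 30,
                                  harboring_samples = 24,
                                  min_decoy_recurrence = 5,
                                  max_decoy_recurrence = 26,
                                  chrom = "chr17", region_start = 38.1e6,
                                  cluster_spacing = 1e6, seed) {
  stopifnot(harboring_samples <= n_samples,
            max_decoy_recurrence <= n_samples)
  withr::with_seed(seed, {
    sample_ids <- sprintf("CL%02d", seq_len(n_samples))
    n_clusters <- n_decoy_clusters + 1
    anchors <- region_start + cluster_spacing * seq_len(n_clusters)
    driver_idx <- 1L
    width <- 20e3

    # per-cluster base strength: the driver towers over every decoy
    base_strength <- c(1000, sort(runif(n_decoy_clusters, 10, 100),
                                  decreasing = TRUE))
    recurrences <- c(harboring_samples,
                     sample(min_decoy_recurrence:max_decoy_recurrence,
                            n_decoy_clusters, replace = TRUE))
    members <- lapply(recurrences, function(k) sample(sample_ids, k))

    calls <- purrr::map_dfr(seq_len(n_clusters), function(i) {
      ids <- members[[i]]
      # member calls jitter inside the planted span; all overlap its middle
      s <- anchors[i] + floor(runif(length(ids), 0, width / 4))
      e <- anchors[i] + width - floor(runif(length(ids), 0, width / 4))
      tibble(sample_id = ids, chrom = chrom, start = s, end = e,
             signal = base_strength[i] * exp(rnorm(length(ids), 0, 0.1)))
    })
    truth_clusters <- tibble(
      cluster = c("driver", sprintf("decoy%02d", seq_len(n_decoy_clusters))),
      chrom = chrom,
      span_start = anchors,
      span_end = anchors + width,
      recurrence = recurrences
    )

    # gene table: one TF at the driver cluster, a non-TF neighbor, and a
    # gene (TF for half of them) near every decoy
    decoy_is_tf <- rep(c(TRUE, FALSE), length.out = n_decoy_clusters)
    genes <- bind_rows(
      tibble(gene_id = "DRIVER_TF", symbol = "DRIVER_TF", chrom = chrom,
             tss = anchors[driver_idx] + width + 50e3, strand = "+",
             is_tf = TRUE),
      tibble(gene_id = "DRIVER_NB", symbol = "DRIVER_NB", chrom = chrom,
             tss = anchors[driver_idx] - 50e3, strand = "+", is_tf = FALSE),
      tibble(gene_id = sprintf("DECOY%02d", seq_len(n_decoy_clusters)),
             symbol = sprintf("DECOY%02d", seq_len(n_decoy_clusters)),
             chrom = chrom,
             tss = anchors[-driver_idx] + width + 50e3,
             strand = "+", is_tf = decoy_is_tf)
    )

    # TSS peaks: every sample marks the driver TSS; each decoy TSS is
    # marked per sample with high probability, so most recurrent decoy TFs
    # survive the active-in-all-harboring-samples filter and compete with
    # the driver, while a few drop out (as in real landscapes)
    tss_peaks <- lapply(sample_ids, function(sid) {
      marked <- genes$tss[c(TRUE, TRUE, runif(n_decoy_clusters) < 0.98)]
      validate_intervals(tibble(chrom = chrom, start = marked - 300,
                                end = marked + 300))
    })
    names(tss_peaks) <- sample_ids

    list(
      se_calls = validate_intervals(calls, "simulated SE calls"),
      genes = genes,
      tss_peaks = tss_peaks,
      truth = list(clusters = truth_clusters, driver_gene = "DRIVER_TF",
                   driver_span = c(anchors[driver_idx],
                                   anchors[driver_idx] + width),
                   sample_ids = sample_ids)
    )
  })
}

#' Simulate a tumor cohort with linked expression, survival and copy number
#'
#' Expression of the driver gene is baseline + `gain_shift` for tumors with
#' arm gain, plus Gaussian noise; all other genes are pure noise. Survival
#' times are exponential with per-sample hazard
#' `baseline_hazard * hr^z`, `z` the standardized driver expression, under
#' independent exponential censoring. Copy-number segments cover the whole
#' arm with log2 ratio ~ 0.5 for gained tumors and ~ 0 otherwise, and a
#' per-tumor stage table marks high-stage disease.
#'
#' @param n_tumors Cohort size.
#' @param gene_ids Genes to simulate (must include `driver_gene`).
#' @param driver_gene The dosage-sensitive driver.
#' @param hr Hazard ratio per standard deviation of driver expression.
#' @param gain_fraction Fraction of tumors with arm gain.
#' @param gain_shift Expression shift (log2 units) in gained tumors.
#' @param stage_high_fraction Fraction of high-stage tumors.
#' @param baseline_hazard Baseline event hazard per day.
#' @param censoring_rate Independent censoring hazard per day.
#' @param noise_sd Expression noise standard deviation (log2 units).
#' @param baseline_expression Mean log2 expression of every gene.
#' @param chrom,arm_start,arm_end Arm coordinates for the segments.
#' @param seed Integer seed (mandatory).
#' @return A list: `expression` (tibble, `gene_id` + tumor columns),
#'   `survival`, `segments`, `stage`, and `truth`.
#' @export
simulate_cohort <- function(n_tumors = 200,
                            gene_ids = c("DRIVER_TF",
                                         sprintf("DECOY%02d", 1:30)),
                            driver_gene = "DRIVER_TF", hr = 2.5,
                            gain_fraction = 0.5, gain_shift = 1,
                            stage_high_fraction = 0.5,
                            baseline_hazard = 1 / 1500,
                            censoring_rate = 1 / 4000, noise_sd = 1,
                            baseline_expression = 8, chrom = "chr17",
                            arm_start = 38.1e6, arm_end = 81e6, seed) {
  stopifnot(driver_gene %in% gene_ids, gain_fraction >= 0,
            gain_fraction <= 1, hr > 0)
  withr::with_seed(seed, {
    tumor_ids <- sprintf("T%03d", seq_len(n_tumors))
    gained <- runif(n_tumors) < gain_fraction
    stage_high <- runif(n_tumors) < stage_high_fraction

    expr <- matrix(rnorm(length(gene_ids) * n_tumors,
                         mean = baseline_expression, sd = noise_sd),
                   nrow = length(gene_ids),
                   dimnames = list(gene_ids, tumor_ids))
    expr[driver_gene, ] <- baseline_expression + gain_shift * gained +
      rnorm(n_tumors, 0, noise_sd)

    z <- as.numeric(scale(expr[driver_gene, ]))
    hazard <- baseline_hazard * hr^z
    t_event <- rexp(n_tumors, rate = hazard)
    t_cens <- rexp(n_tumors, rate = censoring_rate)
    survival <- tibble(sample_id = tumor_ids,
                       time = pmin(t_event, t_cens),
                       event = as.integer(t_event <= t_cens))

    seg_noise <- rnorm(n_tumors, 0, 0.05)
    segments <- tibble(sample_id = tumor_ids, chrom = chrom,
                       start = arm_start, end = arm_end,
                       log2_ratio = if_else(gained, 0.5, 0) + seg_noise)

    expression <- bind_cols(tibble(gene_id = gene_ids),
                            as_tibble(expr))
    list(
      expression = expression,
      survival = survival,
      segments = segments,
      stage = tibble(sample_id = tumor_ids, stage_high = stage_high),
      truth = list(gained = setNames(gained, tumor_ids),
                   stage_high = setNames(stage_high, tumor_ids),
                   driver_gene = driver_gene, hr = hr,
                   gain_shift = gain_shift)
    )
  })
}

#' Simulate a 4C fragment-coverage track
#'
#' Background fragments are covered independently with probability `p_bg`;
#' fragments inside planted interaction windows with probability `p_hi`.
#' Covered fragments receive `1 + Poisson(2)` reads.
#'
#' @param n_fragments Track length in fragments.
#' @param p_bg Background coverage probability.
#' @param planted_windows Tibble (`start`, `width`, `p_hi`) in fragment
#'   indices; windows must lie inside the track and not overlap.
#' @param viewpoint_index Fragment index of the viewpoint.
#' @param chrom Chromosome name.
#' @param fragment_size Mean fragment length (bp) for the coordinates.
#' @param seed Integer seed (mandatory).
#' @return A list: `track` (tibble `chrom`, `start`, `end`, `count`),
#'   `viewpoint_index` and `truth` (planted window index ranges).
#' @export
simulate_fourc_track <- function(n_fragments = 5000, p_bg = 0.05,
                                 planted_windows = NULL,
                                 viewpoint_index = 1L, chrom = "chr17",
                                 fragment_size = 500, seed) {
  stopifnot(p_bg >= 0, p_bg < 1)
  if (is.null(planted_windows)) {
    planted_windows <- tibble(start = integer(), width = integer(),
                              p_hi = double())
  }
  planted_windows <- as_tibble(planted_windows)
  if (nrow(planted_windows) > 0) {
    stopifnot(all(planted_windows$p_hi > p_bg),
              all(planted_windows$p_hi <= 1),
              all(planted_windows$start >= 1),
              all(planted_windows$start + planted_windows$width - 1 <=
                    n_fragments))
    pw <- arrange(planted_windows, .data$start)
    if (nrow(pw) > 1 &&
        any(pw$start[-1] <= (pw$start + pw$width - 1)[-nrow(pw)])) {
      abort("planted windows must not overlap")
    }
  }
  withr::with_seed(seed, {
    p <- rep(p_bg, n_fragments)
    for (i in seq_len(nrow(planted_windows))) {
      idx <- planted_windows$start[i] +
        seq_len(planted_windows$width[i]) - 1L
      p[idx] <- planted_windows$p_hi[i]
    }
    covered <- rbinom(n_fragments, 1, p)
    counts <- covered * (1 + stats::rpois(n_fragments, 2))
    starts <- fragment_size * (seq_len(n_fragments) - 1)
    list(
      track = tibble(chrom = chrom, start = starts,
                     end = starts + fragment_size, count = counts),
      viewpoint_index = viewpoint_index,
      truth = list(planted = mutate(planted_windows,
                                    end = .data$start + .data$width - 1L),
                   p_bg = p_bg)
    )
  })
}

# Hill inhibition curve: fraction inhibited at dose d
hill_inhibition <- function(dose, ec50, slope, emax) {
  if_else(dose == 0, 0, emax * dose^slope / (dose^slope + ec50^slope))
}

#' Simulate a drug-combination checkerboard
#'
#' Single-agent margins follow Hill inhibition curves; combination cells
#' follow exact Bliss independence plus an additive planted `synergy_term`
#' on the Excess-over-Bliss scale, plus Gaussian noise on the inhibition
#' scale; viability is clamped to `[0, 100]`.
#'
#' @param doses_a,doses_b Dose vectors including 0 (ascending). Defaults
#'   are nine-point three-fold dilutions spanning 5.1 nM to 33.3 uM and
#'   0.051 nM to 0.333 uM.
#' @param ec50_a,slope_a,emax_a Hill parameters of drug A.
#' @param ec50_b,slope_b,emax_b Hill parameters of drug B.
#' @param synergy_term Planted Excess over Bliss added to combination
#'   cells (scalar, or matrix over combination cells).
#' @param noise_sd Noise standard deviation on the inhibition scale.
#' @param seed Integer seed (mandatory).
#' @return A list: `checkerboard` (tidy tibble), and `truth` (the planted
#'   noiseless Excess-over-Bliss surface).
#' @export
simulate_checkerboard <- function(doses_a = c(0, 33.3 / 3^(8:0)) * 1e3,
                                  doses_b = c(0, 0.333 / 3^(8:0)) * 1e3,
                                  ec50_a = 1000, slope_a = 1, emax_a = 0.9,
                                  ec50_b = 30, slope_b = 1.2, emax_b = 0.85,
                                  synergy_term = 0, noise_sd = 0, seed) {
  stopifnot(doses_a[1] == 0, doses_b[1] == 0)
  withr::with_seed(seed, {
    ia <- hill_inhibition(doses_a, ec50_a, slope_a, emax_a)
    ib <- hill_inhibition(doses_b, ec50_b, slope_b, emax_b)
    na <- length(doses_a)
    nb <- length(doses_b)
    bliss <- outer(ia, ib, function(a, b) a + b - a * b)
    syn <- matrix(0, na, nb)
    syn[-1, -1] <- synergy_term
    inhibition_true <- pmin(pmax(bliss + syn, 0), 1)
    noise <- matrix(rnorm(na * nb, 0, noise_sd), na, nb)
    noise[1, 1] <- 0  # vehicle control stays at 100%
    viability <- pmin(pmax(100 * (1 - inhibition_true - noise), 0), 100)
    truth_eob <- inhibition_true - bliss
    cb <- as_checkerboard(viability, doses_a, doses_b)
    list(checkerboard = cb,
         truth = list(eob = truth_eob, doses_a = doses_a,
                      doses_b = doses_b))
  })
}
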