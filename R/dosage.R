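# Copy-number dosage analysis: focal gain/amplification detection over a
# locus, per-sample chromosome-arm gain calls, and the ANOVA quantifying how
# much expression variability is explained by tumor stage and copy-number
# status.

#' Detect focal gains over a locus
#'
#' Returns the copy-number segments that overlap the locus by at least 1 bp,
#' have `log2_ratio >= min_log2` (inclusive), and span at most
#' `max_focal_size` bp (inclusive). Segments on other chromosomes are
#' ignored.
#'
#' @param segments Segment tibble (`chrom`, `start`, `end`, `log2_ratio`,
#'   optional `sample_id`).
#' @param locus A single-row interval tibble or a list with `chrom`,
#'   `start`, `end`.
#' @param min_log2 Minimum log2 ratio (default 0.3, inclusive).
#' @param max_focal_size Maximum segment size in bp (default 5 Mb,
#'   inclusive).
#' @return The detected segments with a `size_bp` column.
#' @export
detect_focal_gains <- function(segments, locus, min_log2 = 0.3,
                               max_focal_size = 5e6) {
  stopifnot(min_log2 > 0, max_focal_size > 0)
  segments <- as_tibble(segments)
  segments |>
    filter(.data$chrom == locus$chrom,
           .data$end > locus$start, .data$start < locus$end,
           .data$log2_ratio >= min_log2,
           .data$end - .data$start <= max_focal_size) |>
    mutate(size_bp = .data$end - .data$start)
}

#' Call per-sample chromosome-arm gain
#'
#' A sample is called "gained" when the length-weighted mean log2 ratio of
#' its segments over the arm region exceeds `threshold` (strict `>`).
#' Samples with no segment overlapping the arm get `gained = NA` (unknown)
#' and are excluded from downstream tests.
#'
#' @param segments Segment tibble with a `sample_id` column.
#' @param arm Arm region (single-row interval tibble or list with `chrom`,
#'   `start`, `end`).
#' @param threshold Gain threshold on the weighted mean log2 ratio
#'   (default 0.3, strict).
#' @return A tibble with one row per sample: `sample_id`, `mean_log2`,
#'   `gained`.
#' @export
call_arm_gain <- function(segments, arm, threshold = 0.3) {
  segments <- as_tibble(segments)
  if (!"sample_id" %in% names(segments)) {
    abort("call_arm_gain needs per-sample segments (a 'sample_id' column)")
  }
  overlaps <- segments |>
    filter(.data$chrom == arm$chrom, .data$end > arm$start,
           .data$start < arm$end) |>
    mutate(weight = pmin(.data$end, arm$end) - pmax(.data$start, arm$start))
  means <- overlaps |>
    group_by(.data$sample_id) |>
    summarise(mean_log2 = sum(.data$log2_ratio * .data$weight) /
                sum(.data$weight), .groups = "drop")
  tibble(sample_id = unique(segments$sample_id)) |>
    left_join(means, by = "sample_id") |>
    mutate(gained = if_else(is.na(.data$mean_log2), NA,
                            .data$mean_log2 > threshold))
}

#' Two-way dosage ANOVA of expression on stage and copy-number gain
#'
#' Fits the fixed-effects model `expression ~ stage * gain` and reports
#' type-II sums of squares for the stage and gain main effects and type-III
#' -style interaction (the standard type-II table), together with the
#' headline quantity: the one-way gain effect within the high-stage
#' stratum. Samples with unknown gain status are dropped.
#'
#' @param data A tibble with columns `expression` (numeric), `stage_high`
#'   (logical or two-level factor) and `gained` (logical or two-level
#'   factor).
#' @return An object of class `"dosage_anova"`; see [tidy.dosage_anova()]
#'   and [glance.dosage_anova()].
#' @export
dosage_anova <- function(data) {
  data <- as_tibble(data) |>
    filter(!is.na(.data$gained), !is.na(.data$stage_high),
           !is.na(.data$expression)) |>
    mutate(stage_high = as.logical(.data$stage_high),
           gained = as.logical(.data$gained))
  if (length(unique(data$stage_high)) < 2) abort("factor 'stage' has one level")
  if (length(unique(data$gained)) < 2) abort("factor 'gain' has one level")
  mdat <- mutate(data, stage_high = factor(.data$stage_high),
                 gained = factor(.data$gained))
  fit <- lm(expression ~ stage_high * gained, data = mdat)
  tab <- anova_type2(fit)
  # headline: gain effect among high-stage samples only
  high <- filter(data, .data$stage_high)
  if (length(unique(high$gained)) < 2) {
    high_p <- NA_real_
    high_f <- NA_real_
  } else {
    fit1 <- aov(expression ~ factor(gained), data = high)
    s <- summary(fit1)[[1]]
    high_f <- s[["F value"]][1]
    high_p <- s[["Pr(>F)"]][1]
  }
  structure(list(two_way = tab, fit = fit, n = nrow(data),
                 gain_in_high_stage_F = high_f,
                 gain_in_high_stage_p = high_p),
            class = "dosage_anova")
}

# type-II SS table for a two-factor model with interaction: each main
# effect adjusted for the other main effect (not the interaction), the
# interaction adjusted for both. Uses car::Anova when available, else
# explicit model comparisons (identical answers).
anova_type2 <- function(fit) {
  if (requireNamespace("car", quietly = TRUE)) {
    tab <- car::Anova(fit, type = 2)
    out <- tibble(term = rownames(tab), sumsq = tab[["Sum Sq"]],
                  df = tab[["Df"]], statistic = tab[["F value"]],
                  p_value = tab[["Pr(>F)"]])
    return(filter(out, .data$term != "Residuals") |>
             mutate(term = c("stage", "gain", "stage:gain")))
  }
  data <- fit$model
  rss <- function(form) sum(lm(form, data = data)$residuals^2)
  full_int <- rss(expression ~ stage_high * gained)
  both <- rss(expression ~ stage_high + gained)
  ss_stage <- rss(expression ~ gained) - both
  ss_gain <- rss(expression ~ stage_high) - both
  ss_int <- both - full_int
  df_res <- fit$df.residual
  ms_res <- full_int / df_res
  sumsq <- c(ss_stage, ss_gain, ss_int)
  stat <- sumsq / ms_res
  tibble(term = c("stage", "gain", "stage:gain"), sumsq = sumsq,
         df = c(1L, 1L, 1L), statistic = stat,
         p_value = stats::pf(stat, 1, df_res, lower.tail = FALSE))
}

#' @rdname dosage_anova
#' @param x A `dosage_anova` object.
#' @param ... Unused.
#' @export
print.dosage_anova <- function(x, ...) {
  cat(sprintf("Dosage ANOVA (n = %d)\n", x$n))
  print(x$two_way)
  cat(sprintf("Gain effect within high stage: F = %.4g, p = %.4g\n",
              x$gain_in_high_stage_F, x$gain_in_high_stage_p))
  invisible(x)
}

#' Tidy a dosage ANOVA
#'
#' @param x A `dosage_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per model term (`stage`, `gain`,
#'   `stage:gain`): sum of squares, df, F and p.
#' @export
tidy.dosage_anova <- function(x, ...) x$two_way

#' @rdname tidy.dosage_anova
#' @return For `glance()`: a one-row tibble with `n`, the within-high-stage
#'   gain-effect `gain_in_high_stage_F`/`gain_in_high_stage_p`, and the
#'   two-way interaction p.
#' @export
glance.dosage_anova <- function(x, ...) {
  tibble(n = x$n,
         gain_in_high_stage_F = x$gain_in_high_stage_F,
         gain_in_high_stage_p = x$gain_in_high_stage_p,
         interaction_p = x$two_way$p_value[x$two_way$term == "stage:gain"])
}
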