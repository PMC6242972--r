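# 4C-seq interaction calling on restriction-fragment coverage tracks.
#
# The signal is binarized (a fragment is "covered" when at least one read
# maps to it); for every fragment a z-score compares the covered fraction
# in a small centered window (w fragments) against the covered fraction in
# a large centered background window (W fragments):
#
#   z = (p_w - p_W) / sqrt(p_W (1 - p_W) / n_w)
#
# with n_w the actual (possibly edge-truncated) small-window size and z set
# to 0 where the background fraction is degenerate (0 or 1). One-sided
# upper-tail normal p-values are BH-adjusted across all tested windows of
# the track; calls are significant at FDR 1% in cis and 0.5% in trans.
# Display tracks are smoothed over 21 consecutive fragments and normalized
# per million reads; domainograms show covered fractions across a range of
# window sizes.

#' 4C analysis parameters
#'
#' @param w Small (foreground) window size in fragments.
#' @param W Large (background) window size in fragments.
#' @param fdr_cis FDR threshold for cis interactions.
#' @param fdr_trans FDR threshold for trans interactions.
#' @param smooth_k Smoothing window (fragments, odd) for display tracks.
#' @param viewpoint_exclusion Number of fragments masked on each side of
#'   the viewpoint in cis mode.
#' @return A list of class `"fourc_config"`.
#' @export
fourc_config <- function(w = 100, W = 3000, fdr_cis = 0.01,
                         fdr_trans = 0.005, smooth_k = 21,
                         viewpoint_exclusion = 200) {
  stopifnot(w > 0, W > w, fdr_cis > 0, fdr_cis < 1, fdr_trans > 0,
            fdr_trans < 1, smooth_k %% 2 == 1, viewpoint_exclusion >= 0)
  structure(list(w = w, W = W, fdr_cis = fdr_cis, fdr_trans = fdr_trans,
                 smooth_k = smooth_k,
                 viewpoint_exclusion = viewpoint_exclusion),
            class = "fourc_config")
}

validate_track <- function(track) {
  track <- as_tibble(track)
  needed <- setdiff(c("chrom", "start", "end", "count"), names(track))
  if (length(needed) > 0) {
    abort(sprintf("fragment track: missing column(s) %s",
                  paste(needed, collapse = ", ")))
  }
  if (any(track$count < 0)) abort("fragment counts must be non-negative")
  if (dplyr::n_distinct(track$chrom) > 1) {
    abort("a fragment track covers a single chromosome")
  }
  if (is.unsorted(track$start, strictly = TRUE)) {
    abort("fragment starts must be strictly increasing")
  }
  track
}

#' Binarize fragment coverage
#'
#' A fragment is covered iff at least one read maps to it.
#'
#' @param counts Non-negative integer vector of per-fragment read counts.
#' @return A 0/1 integer vector.
#' @export
binarize <- function(counts) {
  if (any(counts < 0)) abort("fragment counts must be non-negative")
  as.integer(counts >= 1)
}

# covered fraction in centered windows of nominal size k, truncated at the
# track ends; returns list(frac, n) for each center position
windowed_fraction <- function(binary, k) {
  n <- length(binary)
  half_lo <- floor((k - 1) / 2)
  half_hi <- floor(k / 2)
  idx <- seq_len(n)
  lo <- pmax(idx - half_lo, 1L)
  hi <- pmin(idx + half_hi, n)
  cs <- cumsum(binary)
  covered <- cs[hi] - c(0, cs)[lo]
  n_w <- hi - lo + 1L
  list(frac = covered / n_w, n = n_w)
}

#' Sliding-window z-scores on a binarized 4C track
#'
#' For each fragment, compares the covered fraction in the centered
#' `w`-fragment window against the centered `W`-fragment background window
#' with a normal-approximate one-sample proportion statistic. Windows
#' shrink at the track ends; the actual window size enters the variance.
#'
#' @param binary 0/1 coverage vector (from [binarize()]).
#' @param config A [fourc_config()].
#' @return A tibble with one row per fragment position: `index`, `p_w`,
#'   `p_W`, `n_w`, `z`.
#' @export
sliding_zscore <- function(binary, config = fourc_config()) {
  if (length(binary) < config$w) {
    abort(sprintf("track has %d fragments, shorter than the window (w = %d)",
                  length(binary), config$w))
  }
  small <- windowed_fraction(binary, config$w)
  big <- windowed_fraction(binary, config$W)
  z <- (small$frac - big$frac) /
    sqrt(big$frac * (1 - big$frac) / small$n)
  z[big$frac <= 0 | big$frac >= 1] <- 0
  tibble(index = seq_along(binary), p_w = small$frac, p_W = big$frac,
         n_w = small$n, z = z)
}

#' Call significant 4C interactions
#'
#' Converts sliding-window z-scores to one-sided upper-tail normal
#' p-values, adjusts them with Benjamini-Hochberg across all tested
#' windows, and flags windows with `q <= fdr_cis` (cis) or
#' `q <= fdr_trans` (trans). In cis mode the fragments within
#' `viewpoint_exclusion` of the viewpoint are masked before testing
#' (proximity artifacts).
#'
#' @param zscores Tibble from [sliding_zscore()].
#' @param mode `"cis"` or `"trans"`.
#' @param config A [fourc_config()].
#' @param viewpoint_index Fragment index of the viewpoint (required in cis
#'   mode when `viewpoint_exclusion > 0`).
#' @return The input tibble restricted to tested windows, with `p`, `q` and
#'   `significant` columns.
#' @export
call_interactions <- function(zscores, mode = c("cis", "trans"),
                              config = fourc_config(),
                              viewpoint_index = NULL) {
  mode <- match.arg(mode)
  if (any(!is.finite(zscores$z))) abort("z-scores must be finite")
  tested <- zscores
  if (mode == "cis" && config$viewpoint_exclusion > 0 &&
      !is.null(viewpoint_index)) {
    tested <- filter(tested,
                     abs(.data$index - viewpoint_index) >
                       config$viewpoint_exclusion)
  }
  fdr <- if (mode == "cis") config$fdr_cis else config$fdr_trans
  tested |>
    mutate(p = pnorm(.data$z, lower.tail = FALSE),
           q = p.adjust(.data$p, method = "BH"),
           significant = .data$q <= fdr)
}

#' Merge significant windows into maximal runs
#'
#' Consecutive significant window positions are reported as one
#' interaction region.
#'
#' @param calls Tibble from [call_interactions()].
#' @param track Optional fragment track supplying genomic coordinates.
#' @return One row per maximal run: fragment index range, peak z and
#'   minimum q, plus `chrom`/`start`/`end` when a track is given.
#' @export
merge_interaction_calls <- function(calls, track = NULL) {
  sig <- calls |> filter(.data$significant) |> arrange(.data$index)
  if (nrow(sig) == 0) {
    out <- tibble(from = integer(), to = integer(), n_windows = integer(),
                  peak_z = double(), min_q = double())
  } else {
    run_id <- cumsum(c(1L, diff(sig$index) > 1L))
    out <- sig |>
      mutate(run = run_id) |>
      group_by(.data$run) |>
      summarise(from = min(.data$index), to = max(.data$index),
                n_windows = dplyr::n(), peak_z = max(.data$z),
                min_q = min(.data$q), .groups = "drop") |>
      select(-"run")
  }
  if (!is.null(track)) {
    track <- validate_track(track)
    out <- mutate(out, chrom = track$chrom[1],
                  start = track$start[.data$from],
                  end = track$end[.data$to])
  }
  out
}

#' Smooth and library-normalize a fragment track
#'
#' Centered moving average of the raw counts over `smooth_k` consecutive
#' fragments (shrinking at the ends), scaled to reads per million by
#' `1e6 / library_size`.
#'
#' @param track Fragment track tibble (`chrom`, `start`, `end`, `count`).
#' @param config A [fourc_config()].
#' @param library_size Total read count used for normalization; defaults
#'   to the sum of the track's counts.
#' @return A bedGraph-shaped tibble (`chrom`, `start`, `end`, `value`).
#' @export
smooth_track <- function(track, config = fourc_config(),
                         library_size = NULL) {
  track <- validate_track(track)
  library_size <- library_size %||% sum(track$count)
  if (library_size <= 0) abort("library_size must be positive")
  k <- config$smooth_k
  n <- nrow(track)
  half <- (k - 1) / 2
  idx <- seq_len(n)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, n)
  cs <- cumsum(track$count)
  avg <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
  tibble(chrom = track$chrom, start = track$start, end = track$end,
         value = avg * 1e6 / library_size)
}

#' Multi-scale domainogram of windowed coverage
#'
#' For every window size in `window_sizes` and every fragment position,
#' the covered fraction of the centered (edge-truncated) window. The row
#' for window size `w` reproduces exactly the `p_w` used by
#' [sliding_zscore()].
#'
#' @param binary 0/1 coverage vector.
#' @param window_sizes Ascending integer vector of window sizes.
#' @return A tibble in long form: `window_size`, `index`, `fraction`
#'   (values in `[0, 1]`).
#' @export
domainogram <- function(binary, window_sizes) {
  stopifnot(!is.unsorted(window_sizes), all(window_sizes >= 1))
  purrr::map_dfr(window_sizes, function(k) {
    wf <- windowed_fraction(binary, k)
    tibble(window_size = k, index = seq_along(binary), fraction = wf$frac)
  })
}

#' Plot a domainogram
#'
#' @param dg Long-form domainogram tibble from [domainogram()].
#' @return A ggplot heat map (position by window size, fill = covered
#'   fraction).
#' @export
plot_domainogram <- function(dg) {
  ggplot2::ggplot(dg, ggplot2::aes(x = .data$index,
                                   y = factor(.data$window_size),
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Fragment index", y = "Window size (fragments)",
                  fill = "Covered\nfraction") +
    ggplot2::theme_minimal()
}
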