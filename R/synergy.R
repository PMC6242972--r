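# Excess-over-Bliss drug-synergy scoring.
#
# A checkerboard is the tidy long form of a dose-by-dose viability matrix:
# one row per (dose_a, dose_b) cell with viability as percent of the
# vehicle control; dose 0 rows/columns are the single-agent margins and
# the (0, 0) cell is the control itself. Inhibition is i = 1 - v/100; the
# Bliss-independence expectation for a combination is
# e = i_a + i_b - i_a * i_b, and the Excess over Bliss is the observed
# combination inhibition minus e (> 0 synergy, < 0 antagonism).

#' Clamp viability percentages at 100
#'
#' Values above 100% (over the vehicle control) are replaced by 100 so
#' inhibitions stay in `[0, 1]` for the Bliss computation. Negative
#' viability indicates an upstream normalization bug and is an error.
#'
#' @param viability Numeric vector or matrix of viability percentages.
#' @return The clamped values, same shape.
#' @export
clamp_viability <- function(viability) {
  if (any(viability < 0, na.rm = TRUE)) {
    abort("negative viability: inputs must be percent of control (>= 0)")
  }
  pmin(viability, 100)
}

#' Convert a viability matrix to a tidy checkerboard
#'
#' @param mat Viability matrix (%), rows indexed by `doses_a`, columns by
#'   `doses_b`; row/column 1 are the single agents (dose 0 of the other
#'   drug) and `mat[1, 1]` the vehicle control.
#' @param doses_a,doses_b Ascending dose vectors starting at 0.
#' @return A tidy tibble (`dose_a`, `dose_b`, `viability`).
#' @export
as_checkerboard <- function(mat, doses_a, doses_b) {
  stopifnot(nrow(mat) == length(doses_a), ncol(mat) == length(doses_b),
            doses_a[1] == 0, doses_b[1] == 0,
            !is.unsorted(doses_a), !is.unsorted(doses_b))
  tibble(dose_a = rep(doses_a, times = length(doses_b)),
         dose_b = rep(doses_b, each = length(doses_a)),
         viability = as.vector(mat))
}

#' Excess-over-Bliss surface of a checkerboard
#'
#' Clamps viability at 100%, derives per-cell inhibitions, and scores every
#' combination cell against the Bliss-independence expectation formed from
#' its single-agent margins. Margin cells score exactly 0 by construction.
#'
#' @param checkerboard Tidy checkerboard tibble (`dose_a`, `dose_b`,
#'   `viability`); must contain the dose-0 margins.
#' @return A tibble of class `"bliss_surface"`: the checkerboard plus
#'   `inhibition`, `expected_inhibition` and `eob` columns (`eob` in
#'   `[-1, 1]`).
#' @export
excess_over_bliss <- function(checkerboard) {
  cb <- as_tibble(checkerboard)
  needed <- setdiff(c("dose_a", "dose_b", "viability"), names(cb))
  if (length(needed) > 0) {
    abort(sprintf("checkerboard: missing column(s) %s",
                  paste(needed, collapse = ", ")))
  }
  cb$viability <- clamp_viability(cb$viability)
  margin_a <- cb |> filter(.data$dose_b == 0) |>
    select("dose_a", va = "viability")
  margin_b <- cb |> filter(.data$dose_a == 0) |>
    select("dose_b", vb = "viability")
  if (nrow(margin_a) == 0 || nrow(margin_b) == 0) {
    abort("checkerboard must contain the single-agent (dose 0) margins")
  }
  out <- cb |>
    left_join(margin_a, by = "dose_a") |>
    left_join(margin_b, by = "dose_b")
  if (anyNA(out$va) || anyNA(out$vb)) {
    abort("missing single-agent margin for some dose")
  }
  out <- out |>
    mutate(
      inhibition = 1 - .data$viability / 100,
      ia = 1 - .data$va / 100,
      ib = 1 - .data$vb / 100,
      expected_inhibition = .data$ia + .data$ib - .data$ia * .data$ib,
      eob = .data$inhibition - .data$expected_inhibition
    ) |>
    select("dose_a", "dose_b", "viability", "inhibition",
           "expected_inhibition", "eob")
  structure(out, class = c("bliss_surface", class(out)))
}

#' Excess over Bliss at one time point of a confluency time course
#'
#' For fixed-dose growth curves (e.g. IncuCyte confluency), the
#' per-condition effect at the chosen time point is
#' `1 - confluency / control` floored at 0 (growth above the control is
#' treated as no inhibition), and the Excess over Bliss is computed from
#' the two single-agent effects and the combination effect.
#'
#' @param timecourse Tibble with columns `time`, `control`, `drug_a`,
#'   `drug_b`, `combination` (confluency or viability, same units).
#' @param timepoint The time at which to score (must match a row).
#' @return A one-row tibble: effects of A, B, the combination, the Bliss
#'   expectation and `eob`.
#' @export
eob_timecourse <- function(timecourse, timepoint) {
  tc <- as_tibble(timecourse)
  row <- filter(tc, .data$time == timepoint)
  if (nrow(row) != 1) {
    abort(sprintf("timepoint %s absent from the time course", timepoint))
  }
  if (row$control <= 0) abort("control confluency must be positive")
  eff <- function(v) max(1 - v / row$control, 0)
  ia <- eff(row$drug_a)
  ib <- eff(row$drug_b)
  ic <- eff(row$combination)
  e <- ia + ib - ia * ib
  tibble(time = timepoint, effect_a = ia, effect_b = ib,
         effect_combination = ic, expected_inhibition = e, eob = ic - e)
}

#' Plot an Excess-over-Bliss surface
#'
#' @param object A `bliss_surface` from [excess_over_bliss()].
#' @param ... Unused.
#' @return A ggplot dose-by-dose tile plot filled by Excess over Bliss.
#' @export
autoplot.bliss_surface <- function(object, ...) {
  combo <- filter(object, .data$dose_a > 0, .data$dose_b > 0)
  ggplot2::ggplot(combo,
                  ggplot2::aes(x = factor(.data$dose_a),
                               y = factor(.data$dose_b),
                               fill = .data$eob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "Dose drug A", y = "Dose drug B",
                  fill = "Excess\nover Bliss") +
    ggplot2::theme_minimal()
}
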