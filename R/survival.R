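# Kaplan-Meier stratification at the median expression cut-off and the
# two-group log-rank test used to rank candidate genes. The estimator and
# test statistic are computed by the survival package (survfit/survdiff);
# this module defines the median-split rule, the result container and its
# tidiers.

#' Split samples at the median expression
#'
#' Samples strictly above the median are labelled `"high"`, samples at or
#' below the median `"low"` (ties go to the low group). A constant vector
#' cannot be split and raises an error.
#'
#' @param x Numeric expression vector (optionally named by sample).
#' @return A factor of `"low"`/`"high"` labels aligned with `x`.
#' @export
median_split <- function(x) {
  if (length(x) < 4) abort("median_split needs at least 4 samples")
  if (anyNA(x)) abort("median_split: missing expression values")
  m <- median(x)
  labels <- if_else(x > m, "high", "low")
  if (length(unique(labels)) < 2) {
    abort("no split possible: expression is constant (or all at the median)")
  }
  factor(labels, levels = c("low", "high"))
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' Computes the standard two-group log-rank statistic
#' \eqn{(\sum (O - E))^2 / \sum V} over the distinct event times, its
#' chi-square (1 df) p-value, and the per-group product-limit survival
#' curves. Events are assumed to precede censoring at tied times (the
#' standard convention).
#'
#' @param survival_data Survival tibble (`sample_id`, `time`, `event`) with
#'   rows aligned to `labels`.
#' @param labels Two-level grouping aligned with the rows of
#'   `survival_data` (e.g. from [median_split()]).
#' @return An object of class `"km_logrank"` with elements `statistic`
#'   (chi-square, 1 df), `p_value`, `n` per group, `curves` (tidy KM step
#'   functions) and `observed`/`expected` per group.
#' @export
km_logrank <- function(survival_data, labels) {
  survival_data <- validate_survival(survival_data)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (length(labels) != nrow(survival_data)) {
    abort("labels must align with the rows of the survival table")
  }
  if (nlevels(labels) != 2) {
    abort("log-rank test needs exactly two non-empty groups")
  }
  if (sum(survival_data$event) == 0) {
    abort("log-rank statistic undefined: no events observed")
  }
  dat <- tibble(time = survival_data$time, event = survival_data$event,
                group = labels)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = dat)
  stat <- unname(sd_fit$chisq)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  strata_names <- sub("^group=", "", rep(names(sf$strata),
                                         times = sf$strata))
  curves <- tibble(group = strata_names, time = sf$time,
                   n_risk = sf$n.risk, n_event = sf$n.event,
                   survival = sf$surv, std_err = sf$std.err)
  structure(list(statistic = stat, p_value = p,
                 n = table(labels),
                 observed = setNames(sd_fit$obs, levels(labels)),
                 expected = setNames(sd_fit$exp, levels(labels)),
                 curves = curves),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat("Two-group log-rank test\n")
  cat(sprintf("  n = %s; observed = %s; expected = %s\n",
              paste(sprintf("%s:%d", names(x$n), x$n), collapse = ", "),
              paste(round(x$observed, 2), collapse = "/"),
              paste(round(x$expected, 2), collapse = "/")))
  cat(sprintf("  chisq = %.4g (1 df), p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Tidy Kaplan-Meier curves from a log-rank result
#'
#' @param x A `km_logrank` object.
#' @param ... Unused.
#' @return The per-group KM step function as a tibble (`group`, `time`,
#'   `n_risk`, `n_event`, `survival`, `std_err`).
#' @export
tidy.km_logrank <- function(x, ...) x$curves

#' @rdname tidy.km_logrank
#' @return For `glance()`: a one-row tibble with the chi-square statistic,
#'   its p-value and the group sizes.
#' @export
glance.km_logrank <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_low = as.integer(x$n[1]), n_high = as.integer(x$n[2]))
}

#' Plot Kaplan-Meier curves
#'
#' @param object A `km_logrank` object.
#' @param ... Unused.
#' @return A ggplot with one survival step function per group, annotated
#'   with the log-rank p-value.
#' @export
autoplot.km_logrank <- function(object, ...) {
  curves <- object$curves |>
    group_by(.data$group) |>
    dplyr::group_modify(~ bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L, survival = 1,
             std_err = 0),
      .x
    )) |>
    ungroup()
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = Inf, y = 1, hjust = 1.1, vjust = 1,
                      label = sprintf("log-rank p = %.3g", object$p_value)) +
    ggplot2::labs(x = "Time", y = "Survival probability",
                  colour = "Expression") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
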