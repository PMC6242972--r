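# Rank-based expression signature scoring and the correlation-test
# selection rule (Pearson when the homoscedasticity assumption holds,
# Spearman otherwise).

#' Construct a gene signature
#'
#' @param up_genes Character vector of up-regulated genes (non-empty).
#' @param down_genes Optional character vector of down-regulated genes;
#'   must not intersect `up_genes`.
#' @return A list of class `"gene_signature"`.
#' @export
gene_signature <- function(up_genes, down_genes = character()) {
  up_genes <- unique(as.character(up_genes))
  down_genes <- unique(as.character(down_genes))
  if (length(up_genes) == 0) abort("a signature needs at least one up gene")
  overlap <- intersect(up_genes, down_genes)
  if (length(overlap) > 0) {
    abort(sprintf("genes in both directions: %s",
                  paste(head(overlap, 3), collapse = ", ")))
  }
  structure(list(up = up_genes, down = down_genes),
            class = "gene_signature")
}

#' Read a two-column signature file
#'
#' Tab-separated `gene` / `direction` (`up` or `down`), with header.
#'
#' @param path Path to the TSV file.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene", "direction") %in% names(x))) {
    abort(sprintf("%s: signature files need 'gene' and 'direction' columns",
                  path))
  }
  if (!all(x$direction %in% c("up", "down"))) {
    abort(sprintf("%s: direction must be 'up' or 'down'", path))
  }
  gene_signature(x$gene[x$direction == "up"],
                 x$gene[x$direction == "down"])
}

#' Rank-based signature score per sample
#'
#' Within each sample, all genes are ranked by expression (1 = lowest,
#' average ranks for ties) and the ranks rescaled to `[0, 1]` as
#' `(r - 1) / (G - 1)`. The score is the mean rescaled rank of the up
#' genes minus the mean rescaled rank of the down genes; with no down
#' genes the score is centered instead as mean up rank minus 0.5. Scores
#' are invariant under any monotone transform of a sample's expression.
#'
#' @param expression Expression tibble (`gene_id` + one numeric column per
#'   sample).
#' @param signature A [gene_signature()] (or list with `up`/`down`).
#' @return A tibble (`sample_id`, `score`).
#' @export
signature_score <- function(expression, signature) {
  expression <- as_tibble(expression)
  up <- intersect(signature$up, expression$gene_id)
  down <- intersect(signature$down, expression$gene_id)
  missing_genes <- setdiff(c(signature$up, signature$down),
                           expression$gene_id)
  if (length(up) == 0) {
    abort("no up-signature gene present in the expression matrix")
  }
  if (length(missing_genes) > 0) {
    warn(sprintf("%d signature gene(s) absent from the matrix: %s%s",
                 length(missing_genes),
                 paste(head(missing_genes, 5), collapse = ", "),
                 if (length(missing_genes) > 5) ", ..." else ""))
  }
  samples <- names(expression)[-1]
  G <- nrow(expression)
  if (G < 2) abort("need at least two genes to rank")
  scores <- vapply(samples, function(s) {
    r <- rank(expression[[s]])
    scaled <- (r - 1) / (G - 1)
    up_mean <- mean(scaled[expression$gene_id %in% up])
    if (length(down) > 0) {
      up_mean - mean(scaled[expression$gene_id %in% down])
    } else {
      up_mean - 0.5
    }
  }, numeric(1))
  tibble(sample_id = samples, score = unname(scores))
}

#' Correlation with automatic Pearson/Spearman selection
#'
#' Assesses homoscedasticity of the `y ~ x` residuals with a
#' Breusch-Pagan test at `alpha`; when not rejected the parametric
#' Pearson correlation is reported, otherwise the non-parametric Spearman
#' correlation.
#'
#' @param x,y Paired numeric vectors (>= 5 complete observations).
#' @param alpha Significance level of the homoscedasticity test.
#' @return A one-row tibble: `method`, `estimate` (r or rho), `p_value`,
#'   `n`, and the Breusch-Pagan p-value `bp_p`.
#' @export
correlate <- function(x, y, alpha = 0.05) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 5) abort("correlate needs at least 5 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in input")
  bp <- lmtest::bptest(lm(y ~ x))
  method <- if (bp$p.value >= alpha) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  tibble(method = method, estimate = unname(ct$estimate),
         p_value = ct$p.value, n = length(x),
         bp_p = unname(bp$p.value))
}
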