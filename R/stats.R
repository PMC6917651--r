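#' One-way ANOVA and pairwise comparisons from summary statistics
#'
#' Reconstructs the omnibus one-way ANOVA from per-group means, SEMs and
#' sample sizes (between-group sum of squares from the means and ns,
#' within-group sum of squares from `sd = SEM * sqrt(n)`), and computes
#' pairwise Welch t-tests between all group pairs. Pairwise p-values are
#' reported uncorrected by default, with an optional multiplicity
#' correction.
#'
#' @param summaries A data frame with columns `group`, `mean`, `sem`, `n`
#'   (k >= 2 groups, each with `n >= 2` and `sem > 0`).
#' @param alpha Significance level for the `significant` flag (default 0.01).
#' @param p_adjust Method passed to [stats::p.adjust()] for the pairwise
#'   p-values; `"none"` (default) matches the uncorrected presentation.
#' @return An object of class `group_comparison`: list with `anova` (one-row
#'   tibble: `f`, `df1`, `df2`, `p`, `significant`) and `pairwise` (tibble:
#'   `group1`, `group2`, `estimate`, `t`, `df`, `p`, `significant`).
#' @export
compare_groups <- function(summaries, alpha = 0.01, p_adjust = "none") {
  req <- c("group", "mean", "sem", "n")
  if (!all(req %in% names(summaries))) {
    stop("summaries needs columns group, mean, sem, n", call. = FALSE)
  }
  k <- nrow(summaries)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(summaries$n < 2) || any(summaries$sem <= 0)) {
    stop("every group needs n >= 2 and sem > 0", call. = FALSE)
  }
  m <- summaries$mean
  n <- summaries$n
  sdv <- summaries$sem * sqrt(n)
  grand <- sum(n * m) / sum(n)
  ss_between <- sum(n * (m - grand)^2)
  ss_within <- sum((n - 1) * sdv^2)
  df1 <- k - 1
  df2 <- sum(n) - k
  f <- (ss_between / df1) / (ss_within / df2)
  p_omni <- stats::pf(f, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(k, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se2 <- summaries$sem[i1]^2 + summaries$sem[i2]^2
    tval <- (m[i1] - m[i2]) / sqrt(se2)
    dfw <- se2^2 / (summaries$sem[i1]^4 / (n[i1] - 1) +
                    summaries$sem[i2]^4 / (n[i2] - 1))
    tibble::tibble(group1 = as.character(summaries$group[i1]),
                   group2 = as.character(summaries$group[i2]),
                   estimate = m[i1] - m[i2], t = tval, df = dfw,
                   p = 2 * stats::pt(abs(tval), dfw, lower.tail = FALSE))
  })
  pw$p <- stats::p.adjust(pw$p, method = p_adjust)
  pw$significant <- pw$p < alpha
  structure(list(
    anova = tibble::tibble(f = f, df1 = df1, df2 = df2, p = p_omni,
                           significant = p_omni < alpha),
    pairwise = pw,
    alpha = alpha
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  a <- x$anova
  cat(sprintf("<group_comparison> F(%d, %d) = %.2f, p = %.3g%s\n",
              a$df1, a$df2, a$f, a$p,
              if (a$significant) " *" else ""))
  print(x$pairwise)
  invisible(x)
}
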