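#' Paired comparison of coupling indices
#'
#' Friedman test for repeated measures across the per-epoch index columns
#' (Px, Pxl, Pxk or any subset of at least two), followed by pairwise
#' Wilcoxon signed-rank tests with Bonferroni correction. Incomplete rows
#' are dropped with a message; at least 10 complete rows are required.
#'
#' @param results A `data.frame` with columns among `Px`, `Pxl`, `Pxk` (e.g.
#'   the output of [run_grid()]), or a list of `rsa_coupling` objects.
#' @param which Index columns to compare (default all three).
#' @param alpha Significance level for the pairwise flags (default 0.05).
#' @return Object of class `rsa_comparison`: `test_name`, `statistic`,
#'   `p_value`, `pairwise` (data.frame: pair, raw p, Bonferroni-adjusted p,
#'   significance flag), `stars` (named map pair -> "*", "**", "***" or
#'   "ns").
#' @export
compare_indices <- function(results, which = c("Px", "Pxl", "Pxk"), alpha = 0.05) {
  if (is.list(results) && !is.data.frame(results) &&
      all(vapply(results, inherits, logical(1L), "rsa_coupling"))) {
    results <- do.call(rbind, lapply(results, function(r) {
      data.frame(Px = r$Px, Pxl = r$Pxl, Pxk = r$Pxk)
    }))
  }
  which <- match.arg(which, c("Px", "Pxl", "Pxk"), several.ok = TRUE)
  if (length(which) < 2L) stop("need at least two indices to compare")
  m <- as.matrix(results[, which, drop = FALSE])
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    message(sprintf("dropping %d incomplete epoch(s)", sum(!complete)))
    m <- m[complete, , drop = FALSE]
  }
  if (nrow(m) < 10L) stop("need at least 10 complete epochs")
  ft <- stats::friedman.test(m)
  stat <- unname(ft$statistic)
  pval <- ft$p.value
  if (!is.finite(stat)) {  # fully tied rows: no rank differences at all
    stat <- 0
    pval <- 1
  }
  pairs <- utils::combn(which, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    p <- safe_p(stats::wilcox.test(m[, pr[1L]], m[, pr[2L]], paired = TRUE,
                                   exact = FALSE))
    data.frame(pair = paste(pr, collapse = " vs "), p_raw = p)
  }))
  finish_report("friedman", stat, pval, pw, alpha)
}

#' Group comparison of a coupling index
#'
#' Kruskal-Wallis test across independent groups (e.g. sleep stages or
#' coupling-level bins), followed by pairwise Wilcoxon rank-sum tests with
#' Bonferroni correction.
#'
#' @param values_by_group Named list mapping group label to a numeric vector
#'   (each of length >= 5).
#' @param alpha Significance level for the pairwise flags.
#' @return An `rsa_comparison` (see [compare_indices()]).
#' @export
compare_groups <- function(values_by_group, alpha = 0.05) {
  if (!is.list(values_by_group) || length(values_by_group) < 2L) {
    stop("need a named list of at least two groups")
  }
  if (is.null(names(values_by_group)) || any(!nzchar(names(values_by_group)))) {
    stop("groups must be named")
  }
  sizes <- lengths(values_by_group)
  if (any(sizes < 5L)) stop("every group needs at least 5 values")
  kt <- stats::kruskal.test(values_by_group)
  labs <- names(values_by_group)
  pairs <- utils::combn(labs, 2L, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    p <- safe_p(stats::wilcox.test(values_by_group[[pr[1L]]],
                                   values_by_group[[pr[2L]]], exact = FALSE))
    data.frame(pair = paste(pr, collapse = " vs "), p_raw = p)
  }))
  finish_report("kruskal_wallis", unname(kt$statistic), kt$p.value, pw, alpha)
}

# A Wilcoxon p-value, with fully tied input (no usable differences) read as
# "no evidence of a difference" (p = 1) rather than an error.
safe_p <- function(expr) {
  p <- tryCatch(suppressWarnings(expr)$p.value, error = function(e) 1)
  if (!is.finite(p)) 1 else p
}

# Shared Bonferroni + star assembly.
finish_report <- function(test_name, statistic, p_value, pw, alpha) {
  pw$p_adjusted <- pmin(1, pw$p_raw * nrow(pw))
  pw$significant <- !is.na(pw$p_adjusted) & pw$p_adjusted < alpha
  stars <- vapply(pw$p_adjusted, p_stars, character(1L))
  names(stars) <- pw$pair
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, pairwise = pw, stars = stars),
            class = "rsa_comparison")
}

#' Significance stars for an adjusted p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `"ns"` otherwise.
#' @param p Adjusted p-value.
#' @return Character star code.
#' @export
p_stars <- function(p) {
  if (!is.finite(p)) return("ns")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' @export
print.rsa_comparison <- function(x, ...) {
  cat(sprintf("<rsa_comparison> %s: statistic = %.4g, p = %.3g\n",
              x$test_name, x$statistic, x$p_value))
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("  %-14s p_adj = %.3g %s\n", x$pairwise$pair[i],
                x$pairwise$p_adjusted[i], x$stars[[i]]))
  }
  invisible(x)
}
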