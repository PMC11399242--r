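#' Paired t-test with effect size
#'
#' Classic paired t on the within-subject differences `a - b`, two-sided
#' p-value from the t distribution with `n - 1` degrees of freedom, and
#' Cohen's d for paired data (`mean(diff) / sd(diff)`).
#'
#' If the differences have zero variance the result is degenerate: all-zero
#' differences give `t = 0, p = 1` with `degenerate = TRUE`; identical
#' nonzero differences are an error (the t statistic is undefined).
#'
#' @param values_a,values_b numeric vectors of equal length >= 3, matched by
#'   subject.
#' @return object of class `comparison_result`: `t`, `df`, `p`,
#'   `effect_size`, `degenerate`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("paired samples must match in length")
  n <- length(values_a)
  if (n < 3L) stop("paired t needs at least 3 subjects")
  if (anyNA(values_a) || anyNA(values_b)) stop("missing values in paired sample")
  d <- values_a - values_b
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1e-300)) {
    if (all(d == 0)) {
      return(structure(list(t = 0, df = n - 1L, p = 1, effect_size = 0,
                            degenerate = TRUE),
                       class = "comparison_result"))
    }
    stop("zero-variance nonzero differences: paired t undefined")
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, effect_size = mean(d) / stats::sd(d),
                 degenerate = FALSE),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.4f, p = %.4g, d = %.3f%s\n", x$df, x$t, x$p,
              x$effect_size, if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

# paired t that degrades gracefully: constant nonzero differences give an
# infinite statistic (maximal paired evidence) instead of an error, so that
# study-level comparison tables never abort on a degenerate metric
paired_t_safe <- function(values_a, values_b) {
  tryCatch(paired_t(values_a, values_b), error = function(e) {
    d <- values_a - values_b
    if (length(d) >= 3L && mean(d) != 0 &&
        stats::sd(d) <= 1e-10 * abs(mean(d))) {
      return(structure(list(t = sign(mean(d)) * Inf, df = length(d) - 1L,
                            p = 0, effect_size = sign(mean(d)) * Inf,
                            degenerate = TRUE),
                       class = "comparison_result"))
    }
    stop(e)
  })
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure at level `q`: sort p-values ascending, find the largest
#' rank `i` with `p(i) <= (i/m) q`, reject all hypotheses of rank <= i.
#' The mask is returned in the original order.
#'
#' @param pvalues numeric vector of p-values in \code{[0, 1]}.
#' @param q FDR level in (0, 1].
#' @param method `"BH"` (default) or `"BY"` (Benjamini-Yekutieli, valid
#'   under arbitrary dependence).
#' @return logical rejection mask, same length and order as `pvalues`.
#' @export
fdr_bh <- function(pvalues, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1) {
    stop("q must lie in (0, 1]")
  }
  if (length(pvalues) == 0L) return(logical(0))
  stats::p.adjust(pvalues, method = method) <= q
}

#' 95% confidence interval of a mean
#'
#' `mean +/- t(0.975, n-1) * sd / sqrt(n)`.
#'
#' @param values numeric vector, length >= 2.
#' @return list with `mean` and `half_width`.
#' @export
ci95 <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  list(mean = mean(values),
       half_width = stats::qt(0.975, n - 1L) * stats::sd(values) / sqrt(n))
}

#' Rich-club curve set
#'
#' Per-subject rich-club curves of one condition on a shared degree-cutoff
#' grid (use [max_common_k()] to find the grid on which every subject's
#' coefficient is defined).
#'
#' @param curves numeric matrix (n_subjects x n_k) of `phi(k)` values; no
#'   missing entries.
#' @param k_values the shared cutoffs (default `0:(n_k-1)`).
#' @return object of class `rich_club_curves`.
#' @export
rich_club_curves <- function(curves, k_values = NULL) {
  curves <- as.matrix(curves)
  if (anyNA(curves)) stop("rich-club curves contain undefined entries")
  if (is.null(k_values)) k_values <- 0:(ncol(curves) - 1L)
  if (length(k_values) != ncol(curves)) stop("k grid does not match curves")
  structure(list(curves = curves, k_values = as.integer(k_values),
                 n_subjects = nrow(curves)),
            class = "rich_club_curves")
}

#' PCA-loading test for rich-club curve differences
#'
#' Rich-club coefficients at neighbouring cutoffs are highly correlated, so
#' instead of testing every cutoff the curves of both conditions are stacked,
#' column-centred, and projected onto their first principal axis; a paired t
#' compares the per-subject PC1 scores between conditions. The PC1 sign is
#' fixed so the mean loading is positive, making a positive t mean "higher
#' curves in condition a".
#'
#' @param cond_a,cond_b [rich_club_curves()] on the same k grid with the
#'   same subjects in the same order.
#' @return `comparison_result` with extra fields `explained_variance`
#'   (fraction of variance on PC1) and `scores_a`, `scores_b`.
#' @export
rich_club_pca_test <- function(cond_a, cond_b) {
  stopifnot(inherits(cond_a, "rich_club_curves"),
            inherits(cond_b, "rich_club_curves"))
  if (!identical(cond_a$k_values, cond_b$k_values)) {
    stop("conditions must share the same k grid")
  }
  if (cond_a$n_subjects != cond_b$n_subjects) {
    stop("conditions must contain the same subjects")
  }
  if (ncol(cond_a$curves) < 2L) stop("need at least 2 cutoffs for PCA")
  stacked <- rbind(cond_a$curves, cond_b$curves)
  pc <- stats::prcomp(stacked, center = TRUE, scale. = FALSE)
  loading <- pc$rotation[, 1L]
  if (mean(loading) < 0) loading <- -loading
  centred <- sweep(stacked, 2L, colMeans(stacked))
  scores <- as.vector(centred %*% loading)
  n <- cond_a$n_subjects
  sa <- scores[seq_len(n)]
  sb <- scores[n + seq_len(n)]
  res <- paired_t_safe(sa, sb)
  res$explained_variance <- pc$sdev[1L]^2 / sum(pc$sdev^2)
  res$scores_a <- sa
  res$scores_b <- sb
  res
}

#' Side-effect rating table
#'
#' Ordinal questionnaire ratings on the 0 (none) to 3 (strong) scale, one
#' per subject, symptom, condition and treatment day.
#'
#' @param ratings integer array, either `subjects x symptoms x conditions`
#'   (already aggregated) or `subjects x symptoms x conditions x days`.
#' @param symptoms,conditions optional dimension labels.
#' @return object of class `side_effect_table`.
#' @export
side_effect_table <- function(ratings, symptoms = NULL, conditions = NULL) {
  if (!(length(dim(ratings)) %in% c(3L, 4L))) {
    stop("ratings must be a 3- or 4-dimensional array")
  }
  if (anyNA(ratings) || any(!(ratings %in% 0:3))) {
    stop("ratings must be integers in {0, 1, 2, 3}")
  }
  dm <- dim(ratings)
  if (is.null(symptoms)) symptoms <- sprintf("symptom%02d", seq_len(dm[2L]))
  if (is.null(conditions)) conditions <- sprintf("cond%d", seq_len(dm[3L]))
  structure(list(ratings = ratings, symptoms = symptoms,
                 conditions = conditions, n_subjects = dm[1L]),
            class = "side_effect_table")
}

#' Pairwise side-effect comparisons with joint FDR
#'
#' Per-day ratings are first averaged over treatment days within subject,
#' then every symptom is compared between every pair of conditions with a
#' paired t-test; Benjamini-Hochberg FDR is applied jointly across all
#' symptom-by-pair tests. Degenerate tests (identical ratings) are reported
#' with `t = 0, p = 1`.
#'
#' @param table [side_effect_table()].
#' @param q FDR level.
#' @return data.frame with one row per symptom and condition pair: `t`,
#'   `df`, `p`, `effect_size`, `significant_after_fdr`.
#' @export
side_effect_comparison <- function(table, q = 0.05) {
  stopifnot(inherits(table, "side_effect_table"))
  r <- table$ratings
  if (length(dim(r)) == 4L) r <- apply(r, c(1L, 2L, 3L), mean)
  n_sym <- dim(r)[2L]
  n_cond <- dim(r)[3L]
  pairs <- utils::combn(n_cond, 2L)
  rows <- list()
  for (s in seq_len(n_sym)) {
    for (pidx in seq_len(ncol(pairs))) {
      i <- pairs[1L, pidx]; j <- pairs[2L, pidx]
      res <- paired_t_safe(r[, s, i], r[, s, j])
      rows[[length(rows) + 1L]] <- data.frame(
        symptom = table$symptoms[s],
        condition_a = table$conditions[i], condition_b = table$conditions[j],
        t = res$t, df = res$df, p = res$p, effect_size = res$effect_size)
    }
  }
  out <- do.call(rbind, rows)
  out$significant_after_fdr <- fdr_bh(out$p, q)
  out
}

#' Association between a graph summary and side-effect strength
#'
#' Pearson correlation across subjects between a per-subject connectivity
#' summary (e.g. the drug-minus-placebo edge-density change) and a
#' per-subject side-effect score, with a two-sided p-value.
#'
#' @param summary_per_subject,sideeffect_score numeric vectors, one entry
#'   per subject.
#' @return list with `r`, `p`, `df`.
#' @export
fc_sideeffect_association <- function(summary_per_subject, sideeffect_score) {
  if (length(summary_per_subject) != length(sideeffect_score)) {
    stop("per-subject vectors must match in length")
  }
  ht <- stats::cor.test(summary_per_subject, sideeffect_score,
                        method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, df = unname(ht$parameter))
}

#' Fraction of a drug eliminated after first-order decay
#'
#' `1 - 2^(-elapsed / half_life)` under single-compartment exponential
#' elimination.
#'
#' @param half_life_h elimination half-life in hours (> 0).
#' @param elapsed_h time since the last dose in hours (> 0).
#' @return fraction in (0, 1).
#' @export
fraction_eliminated <- function(half_life_h, elapsed_h) {
  if (!is.numeric(half_life_h) || any(half_life_h <= 0)) {
    stop("half-life must be positive")
  }
  if (!is.numeric(elapsed_h) || any(elapsed_h <= 0)) {
    stop("elapsed time must be positive")
  }
  1 - 2^(-elapsed_h / half_life_h)
}

#' Write a tidy comparison table as TSV
#'
#' @param df data.frame of comparison results.
#' @param path output file.
#' @export
write_comparison_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
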