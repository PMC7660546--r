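#' Bootstrap Z-score for a term's mean score
#'
#' Compares the mean per-unit score (e.g. foreground RER per CNE) of a term's
#' units against the distribution of means from bootstrap resamples of the
#' same size drawn with replacement from the universe:
#' `Z = (mean(term) - mean(boot means)) / sd(boot means)`. Z > 0 means the
#' term's units are accelerated relative to the universe, Z < 0 constrained.
#'
#' @param values Named numeric vector of per-unit scores (the universe;
#'   `NA` units are dropped).
#' @param term_units Character vector of the term's unit ids (must be a
#'   subset of `names(values)`).
#' @param n_boot Number of bootstrap resamples (default 1500).
#' @param seed Optional integer seed (resampling is deterministic given it).
#' @return Object of class `enrichment_result`: list with `statistic = "zscore"`,
#'   `observed` (the term mean), `z`, `n_units`, `n_boot`, `degenerate`.
#' @export
term_zscore <- function(values, term_units, n_boot = 1500, seed = NULL) {
  stopifnot(n_boot >= 100)
  values <- values[!is.na(values)]
  missing_units <- setdiff(term_units, names(values))
  term_units <- intersect(term_units, names(values))
  if (!length(term_units)) stop("no term unit has an observed value")
  if (!is.null(seed)) set.seed(seed)
  k <- length(term_units)
  obs <- mean(values[term_units])
  boots <- vapply(seq_len(n_boot), function(i)
    mean(values[sample.int(length(values), k, replace = TRUE)]), 0)
  s <- stats::sd(boots)
  degenerate <- !is.finite(s) || s == 0
  z <- if (degenerate) 0 else (obs - mean(boots)) / s
  structure(list(statistic = "zscore", observed = obs, z = z,
                 n_units = k, n_excluded = length(missing_units),
                 n_boot = n_boot, degenerate = degenerate),
            class = "enrichment_result")
}

#' SUMSTAT enrichment of fourth-root likelihood ratios
#'
#' Polygenic enrichment: the observed statistic is the sum of `delta_lnl4`
#' (fourth root of the acceleration likelihood ratio) over the term's units;
#' the empirical p-value compares it to sums of bootstrap resamples of the
#' same size from the universe, with the +1 tie-inclusive correction
#' `p = (1 + #resamples >= observed) / (1 + n_boot)`, so p is never exactly 0.
#'
#' @param results An [accel_scan()] table (needs `element_id`, `delta_lnl4`).
#' @param term_units Character vector of element ids in the term.
#' @param n_boot,seed As in [term_zscore()].
#' @return `enrichment_result` with `statistic = "sumstat"`, `observed`
#'   (sum of delta_lnl4), `p_value`, `n_units`, `n_boot`.
#' @export
sumstat_enrichment <- function(results, term_units, n_boot = 1500,
                               seed = NULL) {
  stopifnot(n_boot >= 100)
  ok <- results$testable & !is.na(results$delta_lnl4)
  scores <- stats::setNames(results$delta_lnl4[ok], results$element_id[ok])
  missing <- setdiff(term_units, names(scores))
  if (length(missing))
    stop("term unit(s) missing from results: ", paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  k <- length(term_units)
  obs <- sum(scores[term_units])
  boots <- vapply(seq_len(n_boot), function(i)
    sum(scores[sample.int(length(scores), k, replace = TRUE)]), 0)
  p <- (1 + sum(boots >= obs - 1e-12)) / (1 + n_boot)
  structure(list(statistic = "sumstat", observed = obs, p_value = p,
                 n_units = k, n_boot = n_boot),
            class = "enrichment_result")
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values: `q_i = min over {j : p_j >= p_i} of (m * p_j / rank_j)`,
#' clipped at 1, input order preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
fdr_correct <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' High-latitude vs sub-Antarctic rate contrast
#'
#' Averages RER over a term's CNE set per extant branch, then performs a
#' one-tailed two-sample t-test of HA > SA on those per-branch means.
#'
#' @param rer An `rer_matrix` from [compute_rer()] (loci x branches).
#' @param term_cnes Character vector of CNE/locus ids (rows).
#' @param tip_classes Named character vector mapping tip label to `"HA"`,
#'   `"SA"` or `"other"`; only terminal branches are used.
#' @param welch Use the Welch (unequal variance) t-test instead of the
#'   pooled-variance test.
#' @return `enrichment_result` with `statistic = "ha_sa_t"`, `t`, `p_value`
#'   (one-tailed, HA > SA), `n_ha`, `n_sa`, and the per-branch means.
#' @export
ha_sa_contrast <- function(rer, term_cnes, tip_classes, welch = FALSE) {
  m <- if (inherits(rer, "rer_matrix")) rer$rer else as.matrix(rer)
  rows <- intersect(term_cnes, rownames(m))
  if (!length(rows)) stop("no term CNE present in the RER matrix")
  ha_tips <- intersect(names(tip_classes)[tip_classes == "HA"], colnames(m))
  sa_tips <- intersect(names(tip_classes)[tip_classes == "SA"], colnames(m))
  branch_mean <- function(tips) {
    v <- colMeans(m[rows, tips, drop = FALSE], na.rm = TRUE)
    v[is.finite(v)]
  }
  ha <- branch_mean(ha_tips)
  sa <- branch_mean(sa_tips)
  if (length(ha) < 2 || length(sa) < 2)
    stop("need >= 2 observed extant branches per class (HA: ", length(ha),
         ", SA: ", length(sa), ")")
  tt <- stats::t.test(ha, sa, alternative = "greater", var.equal = !welch)
  structure(list(statistic = "ha_sa_t", t = unname(tt$statistic),
                 p_value = tt$p.value, n_ha = length(ha), n_sa = length(sa),
                 ha_means = ha, sa_means = sa),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Enrichment (", x$statistic, "): ", sep = "")
  if (x$statistic == "zscore")
    cat(sprintf("Z = %.3f over %d units (%d bootstraps)\n", x$z, x$n_units,
                x$n_boot))
  else if (x$statistic == "sumstat")
    cat(sprintf("sum = %.3f, p = %.4g (%d units, %d bootstraps)\n",
                x$observed, x$p_value, x$n_units, x$n_boot))
  else
    cat(sprintf("t = %.3f, one-tailed p = %.4g (HA n=%d, SA n=%d)\n",
                x$t, x$p_value, x$n_ha, x$n_sa))
  invisible(x)
}
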