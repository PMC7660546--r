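#' Assemble the loci x branches branch-length matrix
#'
#' @param locus_lengths List of [estimate_branch_lengths()] results (or any
#'   list with `locus_id` and a named `lengths` vector).
#' @param master Rooted `phylo` defining the master branch set; columns follow
#'   [branch_ids()] of this tree.
#' @return Object of class `branch_length_matrix`: list with `lengths`
#'   (numeric matrix, loci x branches, `NA` where unobserved), `branch_info`
#'   (data frame: branch_id, terminal flag, tip label where terminal).
#' @export
build_branch_matrix <- function(locus_lengths, master) {
  ids <- branch_ids(master)
  rows <- lapply(locus_lengths, function(x) {
    bad <- setdiff(names(x$lengths), ids)
    if (length(bad))
      stop("locus ", x$locus_id, " has unknown branch ids: ",
           paste(bad, collapse = ", "))
    out <- stats::setNames(rep(NA_real_, length(ids)), ids)
    out[names(x$lengths)] <- x$lengths
    out
  })
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(locus_lengths, function(x) x$locus_id, "")
  ntip <- length(master$tip.label)
  terminal <- master$edge[match(ids, branch_ids(master)), 2] <= ntip
  structure(list(lengths = m,
                 branch_info = data.frame(branch_id = ids,
                                          terminal = terminal,
                                          stringsAsFactors = FALSE)),
            class = "branch_length_matrix")
}

#' Relative evolutionary rates
#'
#' Converts a loci x branches branch-length matrix into relative evolutionary
#' rates (RER): each branch's rate in each locus relative to the genome-wide
#' expectation for that branch. Positive RER means the branch evolved faster
#' than expected at that locus; negative, slower.
#'
#' The computation follows the standard RER recipe: (1) branch lengths below
#' `cutoff` are set missing; (2) each locus row is divided by its row sum
#' (`scale`); (3) the per-branch expectation is the across-locus mean of the
#' scaled lengths; (4) locus values and expectations are transformed
#' (`sqrt` stabilises the variance of short vs long branches); (5) each locus
#' is regressed on the expectations and RER are the standardised residuals.
#' With `weighted = TRUE` the regression is weighted by the inverse of a
#' variance-mean relationship estimated from the pooled unweighted residuals
#' (squared residuals binned by fitted value, isotonic fit across 10 bins) --
#' a heteroskedasticity correction that keeps short- and long-branch RERs on
#' a comparable scale.
#'
#' @param bm A [build_branch_matrix()] result (or plain numeric matrix).
#' @param transform `"sqrt"` or `"none"`.
#' @param weighted Apply the heteroskedasticity weighting.
#' @param scale Divide each locus row by its row sum first.
#' @param cutoff Branch lengths strictly below this are treated as missing
#'   (the default 0 retains all non-negative lengths).
#' @param min_branches Minimum observed branches for a locus to receive RERs.
#' @param min_loci Minimum usable loci (floor for the whole computation).
#' @return Object of class `rer_matrix`: list with `rer` (matrix, same shape),
#'   `expectation`, and `params`.
#' @export
compute_rer <- function(bm, transform = c("sqrt", "none"), weighted = TRUE,
                        scale = TRUE, cutoff = 0, min_branches = 4,
                        min_loci = 10) {
  transform <- match.arg(transform)
  m <- if (inherits(bm, "branch_length_matrix")) bm$lengths else as.matrix(bm)
  if (any(m < 0, na.rm = TRUE)) stop("negative branch lengths")
  m[m < cutoff] <- NA
  usable <- rowSums(!is.na(m)) >= min_branches
  if (sum(usable) < min_loci)
    stop("fewer than ", min_loci, " loci with >= ", min_branches,
         " observed branches")
  if (scale) {
    rs <- rowSums(m, na.rm = TRUE)
    rs[rs == 0] <- 1
    m <- m / rs
  }
  expectation <- colMeans(m[usable, , drop = FALSE], na.rm = TRUE)
  degenerate <- !is.finite(expectation) | expectation < 0
  zero_var <- apply(m[usable, , drop = FALSE], 2, function(x)
    sum(!is.na(x)) >= 2 && stats::var(x, na.rm = TRUE) == 0 &&
      all(x == 0, na.rm = TRUE))
  if (any(zero_var | degenerate))
    warning("branches with degenerate expectation set to missing: ",
            paste(colnames(m)[zero_var | degenerate], collapse = ", "))
  drop_branch <- zero_var | degenerate

  tf <- if (transform == "sqrt") sqrt else identity
  x_all <- tf(expectation)
  y <- tf(m)

  fit_locus <- function(yi, w = NULL) {
    obs <- which(!is.na(yi) & !drop_branch)
    if (length(obs) < min_branches) return(NULL)
    X <- cbind(1, x_all[obs])
    wi <- if (is.null(w)) rep(1, length(obs)) else w[obs]
    fit <- stats::lm.wfit(X, yi[obs], wi)
    list(obs = obs, resid = fit$residuals, fitted = fit$fitted.values, w = wi)
  }

  first <- lapply(seq_len(nrow(m)), function(i)
    if (usable[i]) fit_locus(y[i, ]) else NULL)

  w_branch <- NULL
  if (weighted) {
    fitted_all <- unlist(lapply(first, function(f) f$fitted))
    resid_all <- unlist(lapply(first, function(f) f$resid))
    if (length(fitted_all) >= 20 && stats::sd(fitted_all) > 0) {
      nb <- 10
      br <- unique(stats::quantile(fitted_all, probs = seq(0, 1, length = nb + 1)))
      bins <- cut(fitted_all, br, include.lowest = TRUE)
      v <- tapply(resid_all^2, bins, mean)
      ctr <- tapply(fitted_all, bins, mean)
      ok <- is.finite(v) & is.finite(ctr)
      if (sum(ok) >= 2) {
        iso <- stats::isoreg(ctr[ok], v[ok])
        vfun <- stats::approxfun(iso$x, iso$yf, rule = 2)
        vhat <- pmax(vfun(x_all), max(1e-12, min(v[ok]) * 1e-3))
        w_branch <- 1 / vhat
      }
    }
  }

  rer <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    if (!usable[i]) next
    f <- if (is.null(w_branch)) first[[i]] else fit_locus(y[i, ], w_branch)
    if (is.null(f)) next
    s <- sqrt(sum(f$w * f$resid^2) / sum(f$w))
    rer[i, f$obs] <- if (s < 1e-10) 0 else f$resid / s
  }
  structure(list(rer = rer, expectation = expectation,
                 params = list(transform = transform, weighted = weighted,
                               scale = scale, cutoff = cutoff)),
            class = "rer_matrix")
}

#' @export
print.rer_matrix <- function(x, ...) {
  cat(sprintf("RER matrix: %d loci x %d branches (%s transform, weighted=%s)\n",
              nrow(x$rer), ncol(x$rer), x$params$transform, x$params$weighted))
  invisible(x)
}
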