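#' Per-locus maximum-likelihood branch lengths on a fixed topology
#'
#' Re-estimates every branch length of `tree` for one locus alignment, holding
#' the topology and the substitution model fixed. Optimisation is
#' coordinate-wise: cached pre/post-order partial likelihoods make each branch
#' a cheap one-dimensional bounded problem (Brent), and sweeps repeat until
#' lengths stabilise. Species entirely missing from the alignment keep the full
#' topology (their subtree is marginalised) and their terminal branches are
#' reported as `NA`.
#'
#' @param alignment See [prune_loglik()].
#' @param tree Rooted `phylo` giving the fixed topology (its branch lengths
#'   seed the optimiser when present).
#' @param model A [subst_model][hky_model].
#' @param max_len Upper bound on any branch length (substitutions/site).
#' @param tol Relative convergence tolerance on the log-likelihood.
#' @param min_sweeps,max_sweeps Bounds on the number of coordinate sweeps.
#' @param locus_id Optional identifier carried into the result.
#' @return An object of class `locus_branch_lengths`: list with `locus_id`,
#'   `lengths` (named by [branch_ids()]; `NA` for unresolvable branches),
#'   `loglik`, `n_sites`, `converged`, and `at_bound` (ids of branches that
#'   hit `max_len`).
#' @export
estimate_branch_lengths <- function(alignment, tree, model = jc_model(),
                                    max_len = 10, tol = 1e-6,
                                    min_sweeps = 2, max_sweeps = 20,
                                    locus_id = NA_character_) {
  states <- aln_states(alignment)
  if (ncol(states) == 0L) stop("alignment has no sites")
  extra <- setdiff(rownames(states), tree$tip.label)
  if (length(extra))
    stop("alignment tips absent from tree: ", paste(extra, collapse = ", "))
  st <- tree_struct(tree)
  full <- matrix(0L, st$ntip, ncol(states),
                 dimnames = list(st$tree$tip.label, NULL))
  have <- intersect(st$tree$tip.label, rownames(states))
  full[have, ] <- states[have, ]
  missing_tip <- rowSums(full > 0L) == 0L
  pd <- compress_patterns(full)
  tipL <- tip_partials(pd$pat)

  lengths <- st$tree$edge.length
  if (is.null(lengths)) lengths <- rep(0.1, nrow(st$edge))
  lengths <- pmin(pmax(lengths, 1e-8), max_len)
  opt <- optimize_lengths(st, tipL, lengths, model, pd$w, max_len, tol,
                          min_sweeps, max_sweeps)
  lengths <- opt$lengths
  out <- stats::setNames(lengths, st$ids)
  # terminal branches of absent species are unidentifiable
  tip_edges <- st$edge[, 2] <= st$ntip
  out[st$ids[tip_edges][missing_tip[st$edge[tip_edges, 2]]]] <- NA_real_
  structure(list(locus_id = locus_id,
                 lengths = out,
                 loglik = opt$loglik,
                 n_sites = ncol(states),
                 converged = opt$converged,
                 at_bound = st$ids[!is.na(out[st$ids]) &
                                     out[st$ids] >= max_len - 1e-6]),
            class = "locus_branch_lengths")
}

# Coordinate sweeps over branches with partials recomputed once per sweep.
optimize_lengths <- function(st, tipL, lengths, model, w, max_len, tol,
                             min_sweeps, max_sweeps) {
  # Sweeps reuse partials computed at sweep start (Jacobi-style), which is
  # fast but not guaranteed monotone; the best sweep is kept and the loop
  # stops as soon as a sweep fails to improve materially.
  prev_ll <- -Inf
  best_ll <- -Inf
  best_len <- lengths
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    dp <- down_partials(st, tipL, lengths, model)
    U <- up_partials(st, dp, lengths, model)
    for (k in seq_len(nrow(st$edge))) {
      v <- st$edge[k, 2]
      Dv <- if (v <= st$ntip) tipL[[v]] else dp$D[[v]]
      lengths[k] <- newton_branch(U[[v]], Dv, model, w, lengths[k], max_len)$t
    }
    dp <- down_partials(st, tipL, lengths, model)
    ll <- root_loglik(st, dp, model, w)
    if (ll > best_ll) {
      best_ll <- ll
      best_len <- lengths
    }
    if (sweep >= min_sweeps &&
        (ll < prev_ll || abs(ll - prev_ll) < tol * (abs(ll) + 1))) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
  }
  list(lengths = best_len, loglik = best_ll, converged = converged)
}

#' Fit a neutral model from conserved elements
#'
#' Filters elements by length and per-species coverage, concatenates the
#' survivors, and jointly estimates branch lengths and (for HKY) the
#' transition/transversion ratio kappa by maximising the pruning likelihood.
#' Base frequencies are the empirical frequencies of the concatenated data.
#' This mirrors fitting a neutral tree model from long, well-covered elements
#' before testing individual elements against it.
#'
#' @param elements List of alignments (see [prune_loglik()]).
#' @param tree Rooted `phylo` topology (branch lengths, if any, seed the fit).
#' @param min_length Minimum element length in bp (default 250).
#' @param min_coverage Minimum non-gap fraction required of every species
#'   (default 0.85). Species absent from an element count as coverage 0.
#' @param model_type `"HKY"` (empirical frequencies, fitted kappa) or `"JC"`.
#' @param max_sites Concatenation is capped at this many sites (elements are
#'   taken in order until the cap) to bound fitting cost.
#' @param max_len,tol As in [estimate_branch_lengths()].
#' @return A `tree_model`: list with `tree` (fitted branch lengths), `model`,
#'   `n_elements_used`, `n_sites`, `loglik`, and `filter_counts`.
#' @export
fit_neutral_model <- function(elements, tree, min_length = 250,
                              min_coverage = 0.85,
                              model_type = c("HKY", "JC"),
                              max_sites = 50000, max_len = 10, tol = 1e-6) {
  model_type <- match.arg(model_type)
  stopifnot(length(elements) >= 1)
  mats <- lapply(elements, as_char_alignment)
  too_short <- vapply(mats, ncol, 1L) < min_length
  low_cov <- vapply(mats, function(m) {
    cov <- numeric(length(tree$tip.label))
    names(cov) <- tree$tip.label
    present <- intersect(rownames(m), tree$tip.label)
    cov[present] <- rowMeans(matrix(toupper(m[present, , drop = FALSE]) %in%
                                      DNA_STATES, nrow = length(present)))
    any(cov < min_coverage)
  }, TRUE)
  keep <- !too_short & !low_cov
  counts <- c(total = length(mats), too_short = sum(too_short),
              low_coverage = sum(low_cov & !too_short), kept = sum(keep))
  if (!any(keep))
    stop(sprintf(
      "no element passed the filters (%d too short, %d under-covered of %d)",
      counts[["too_short"]], counts[["low_coverage"]], counts[["total"]]))
  kept <- mats[keep]
  cum <- cumsum(vapply(kept, ncol, 1L))
  kept <- kept[seq_len(max(1L, sum(cum <= max_sites)))]
  species <- tree$tip.label
  concat <- do.call(cbind, lapply(kept, function(m) {
    out <- matrix("-", length(species), ncol(m), dimnames = list(species, NULL))
    present <- intersect(rownames(m), species)
    out[present, ] <- m[present, ]
    out
  }))

  if (model_type == "JC") {
    model <- jc_model()
  } else {
    tab <- table(factor(concat[concat %in% DNA_STATES], levels = DNA_STATES))
    model <- hky_model(pi = as.numeric(tab) / sum(tab), kappa = 2)
  }

  st <- tree_struct(tree)
  pd <- compress_patterns(aln_states(concat)[st$tree$tip.label, , drop = FALSE])
  tipL <- tip_partials(pd$pat)
  lengths <- st$tree$edge.length
  if (is.null(lengths)) lengths <- rep(0.1, nrow(st$edge))
  lengths <- pmin(pmax(lengths, 1e-8), max_len)

  ll <- -Inf
  for (round in 1:6) {
    opt <- optimize_lengths(st, tipL, lengths, model, pd$w, max_len, tol,
                            min_sweeps = 1, max_sweeps = 3)
    lengths <- opt$lengths
    if (model_type == "HKY") {
      ok <- stats::optimize(function(k) {
        m2 <- hky_model(pi = model$pi, kappa = k)
        root_loglik(st, down_partials(st, tipL, lengths, m2), m2, pd$w)
      }, c(0.05, 60), maximum = TRUE, tol = 1e-4)
      model <- hky_model(pi = model$pi, kappa = ok$maximum)
    }
    ll_new <- root_loglik(st, down_partials(st, tipL, lengths, model),
                          model, pd$w)
    if (abs(ll_new - ll) < tol * (abs(ll_new) + 1)) { ll <- ll_new; break }
    ll <- ll_new
  }

  fitted <- st$tree
  fitted$edge.length <- lengths
  structure(list(tree = fitted, model = model,
                 n_elements_used = length(kept),
                 n_sites = ncol(concat), loglik = ll,
                 filter_counts = counts),
            class = "tree_model")
}

#' @export
print.tree_model <- function(x, ...) {
  cat(sprintf(
    "Neutral tree model: %d tips, %s, fit on %d element(s) / %d sites (lnL %.2f)\n",
    length(x$tree$tip.label), x$model$name, x$n_elements_used, x$n_sites,
    x$loglik))
  invisible(x)
}

#' @export
print.locus_branch_lengths <- function(x, ...) {
  cat(sprintf(
    "Locus %s: %d branch lengths (%d missing), %d sites, converged: %s\n",
    x$locus_id, length(x$lengths), sum(is.na(x$lengths)), x$n_sites,
    x$converged))
  invisible(x)
}
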