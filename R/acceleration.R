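#' Branch-specific acceleration likelihood-ratio test
#'
#' Tests whether one pre-specified (foreground) branch evolved faster than
#' the neutral model predicts for a single element. The null fixes all branch
#' scales at 1; the alternative maximises the pruning likelihood over a
#' foreground scale `lambda` in `[1, lambda_max]` (one-sided: acceleration
#' only). Because the null lies on the boundary of the alternative, the
#' p-value uses the 1/2 chi-square(0) + 1/2 chi-square(1) mixture: p = 1 when
#' the likelihood ratio is 0, else half the upper chi-square(1) tail.
#'
#' @param alignment Element alignment, see [prune_loglik()].
#' @param neutral A `tree_model` from [fit_neutral_model()] (or a list with
#'   `tree` and `model`).
#' @param foreground Branch id (see [branch_ids()]) to test.
#' @param lambda_max Upper bound for the foreground scale.
#' @param subtree If `TRUE`, the scale is applied to the foreground branch and
#'   every branch of its descendant subtree instead of the single branch.
#' @param element_id Carried into the result.
#' @return Object of class `accel_result`: list with `element_id`, `delta_lnl`
#'   (2 x log-likelihood ratio), `scale_hat`, `p_value`, `delta_lnl4`
#'   (`delta_lnl^(1/4)`), `testable`, `lnl_null`, `lnl_alt`.
#' @export
accel_lrt <- function(alignment, neutral, foreground, lambda_max = 100,
                      subtree = FALSE, element_id = NA_character_) {
  tree <- neutral$tree
  model <- neutral$model
  ids <- branch_ids(tree)
  if (!foreground %in% ids) stop("unknown foreground branch: ", foreground)
  states <- aln_states(alignment)
  if (ncol(states) == 0L) stop("element has no sites")
  extra <- setdiff(rownames(states), tree$tip.label)
  if (length(extra))
    stop("alignment tips absent from tree: ", paste(extra, collapse = ", "))

  st <- tree_struct(tree)
  full <- matrix(0L, st$ntip, ncol(states),
                 dimnames = list(st$tree$tip.label, NULL))
  have <- intersect(st$tree$tip.label, rownames(states))
  full[have, ] <- states[have, ]

  # untestable when every tip below the foreground branch is missing
  fg_edge <- match(foreground, st$ids)
  fg_node <- st$edge[fg_edge, 2]
  below <- descendant_tips(st$tree, fg_node)
  if (all(rowSums(full[below, , drop = FALSE] > 0L) == 0L)) {
    return(structure(list(element_id = element_id, delta_lnl = NA_real_,
                          scale_hat = NA_real_, p_value = NA_real_,
                          delta_lnl4 = NA_real_, testable = FALSE,
                          lnl_null = NA_real_, lnl_alt = NA_real_),
                     class = "accel_result"))
  }
  scaled_edges <- if (subtree) {
    which(st$ids == foreground | st$edge[, 1] %in% subtree_nodes(st, fg_node))
  } else fg_edge

  pd <- compress_patterns(full)
  tipL <- tip_partials(pd$pat)
  base_len <- st$tree$edge.length

  lik_at <- function(lambda) {
    len <- base_len
    len[scaled_edges] <- len[scaled_edges] * lambda
    root_loglik(st, down_partials(st, tipL, len, model), model, pd$w)
  }
  lnl_null <- lik_at(1)
  if (!subtree) {
    # cache partials: only the foreground edge length varies
    dp <- down_partials(st, tipL, base_len, model)
    U <- up_partials(st, dp, base_len, model)
    Dv <- if (fg_node <= st$ntip) tipL[[fg_node]] else dp$D[[fg_node]]
    g <- edge_loglik_fn(U[[fg_node]], Dv, model, pd$w)
    f <- function(lambda) g(base_len[fg_edge] * lambda)
  } else f <- lik_at
  o <- stats::optimize(f, c(1, lambda_max), maximum = TRUE, tol = 1e-6)
  lnl_alt <- max(o$objective, lnl_null)
  scale_hat <- if (o$objective > lnl_null) o$maximum else 1
  delta <- 2 * (lnl_alt - lnl_null)
  if (delta < 1e-8) {
    delta <- 0; scale_hat <- 1; lnl_alt <- lnl_null
  }
  p <- if (delta == 0) 1 else 0.5 * stats::pchisq(delta, df = 1,
                                                  lower.tail = FALSE)
  structure(list(element_id = element_id, delta_lnl = delta,
                 scale_hat = scale_hat, p_value = p,
                 delta_lnl4 = delta^(1 / 4), testable = TRUE,
                 lnl_null = lnl_null, lnl_alt = lnl_alt),
            class = "accel_result")
}

# internal nodes (including fg_node) of the subtree rooted at fg_node
subtree_nodes <- function(st, fg_node) {
  nodes <- fg_node
  stack <- fg_node
  while (length(stack)) {
    n <- stack[[1]]; stack <- stack[-1]
    kids <- st$edge[st$edge[, 1] == n, 2]
    ints <- kids[kids > st$ntip]
    nodes <- c(nodes, ints)
    stack <- c(stack, ints)
  }
  nodes
}

#' Acceleration scan over a set of elements
#'
#' Applies [accel_lrt()] to each element, never aborting the scan: untestable
#' elements (e.g. the whole foreground subtree missing) get `NA` statistics
#' and `testable = FALSE`.
#'
#' @param elements Named list of alignments.
#' @param neutral,foreground,lambda_max,subtree As in [accel_lrt()].
#' @return Data frame, one row per element in input order: `element_id`,
#'   `delta_lnl`, `scale_hat`, `p_value`, `delta_lnl4`, `testable`.
#' @export
accel_scan <- function(elements, neutral, foreground, lambda_max = 100,
                       subtree = FALSE) {
  ids <- names(elements)
  if (is.null(ids)) ids <- sprintf("element_%04d", seq_along(elements))
  rows <- lapply(seq_along(elements), function(i) {
    r <- accel_lrt(elements[[i]], neutral, foreground,
                   lambda_max = lambda_max, subtree = subtree,
                   element_id = ids[i])
    data.frame(element_id = r$element_id, delta_lnl = r$delta_lnl,
               scale_hat = r$scale_hat, p_value = r$p_value,
               delta_lnl4 = r$delta_lnl4, testable = r$testable,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(element_id = character(0), delta_lnl = numeric(0),
                      scale_hat = numeric(0), p_value = numeric(0),
                      delta_lnl4 = numeric(0), testable = logical(0)))
  do.call(rbind, rows)
}

#' @export
print.accel_result <- function(x, ...) {
  cat(sprintf(
    "Acceleration LRT [%s]: dlnL = %.4f, lambda = %.3f, p = %.4g\n",
    x$element_id, x$delta_lnl, x$scale_hat, x$p_value))
  invisible(x)
}
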