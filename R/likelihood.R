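#' Branch identifiers
#'
#' Every edge of a tree is named after its child node: terminal edges take the
#' tip label, internal edges the node label when present (else `N<node>`).
#' These ids key branch-length tables, branch scale vectors and RER matrices.
#'
#' @param tree A rooted `phylo` object.
#' @return Character vector of branch ids, one per row of `tree$edge`.
#' @export
branch_ids <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  ids <- character(length(child))
  tip <- child <= ntip
  ids[tip] <- tree$tip.label[child[tip]]
  internal <- child[!tip]
  lab <- tree$node.label
  got <- if (!is.null(lab)) lab[internal - ntip] else rep("", length(internal))
  got[is.na(got) | !nzchar(got)] <-
    paste0("N", internal[is.na(got) | !nzchar(got)])
  ids[!tip] <- got
  if (anyDuplicated(ids))
    stop("duplicate branch ids; tip and node labels must be unique")
  ids
}

# ---- internal machinery -----------------------------------------------------

# Coerce supported alignment representations to an upper-case character matrix
# (rows = sequences). Accepts a character matrix, a DNAbin matrix/list, or a
# named character vector of equal-length sequences.
as_char_alignment <- function(alignment) {
  if (inherits(alignment, "DNAbin"))
    alignment <- as.character(alignment)
  if (is.character(alignment) && is.null(dim(alignment))) {
    if (is.null(names(alignment))) stop("sequences must be named")
    n <- unique(nchar(alignment))
    if (length(n) != 1) stop("sequences differ in length")
    alignment <- do.call(rbind, strsplit(alignment, ""))
  }
  if (!is.matrix(alignment)) stop("unsupported alignment representation")
  if (is.null(rownames(alignment))) stop("alignment rows must be named")
  toupper(alignment)
}

# Integer state matrix: A,C,G,T -> 1..4; gaps, N and all other ambiguity
# codes -> 0 (missing; partial likelihood 1 in every state).
aln_states <- function(alignment) {
  m <- as_char_alignment(alignment)
  s <- match(m, DNA_STATES)
  s[is.na(s)] <- 0L
  matrix(as.integer(s), nrow = nrow(m), dimnames = dimnames(m))
}

# Collapse alignment columns to unique site patterns with multiplicities.
compress_patterns <- function(states) {
  key <- do.call(paste0, lapply(seq_len(nrow(states)), function(i) states[i, ]))
  uk <- unique(key)
  list(pat = states[, match(uk, key), drop = FALSE],
       w = tabulate(match(key, uk), length(uk)))
}

# Pre-computed traversal structure for a rooted tree.
tree_struct <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  nnode <- ntip + po$Nnode
  edge <- po$edge
  edge_of_child <- integer(nnode)
  edge_of_child[edge[, 2]] <- seq_len(nrow(edge))
  list(tree = po, ntip = ntip, nnode = nnode, edge = edge,
       root = ntip + 1L,
       edge_of_child = edge_of_child,
       children = split(edge[, 2], factor(edge[, 1], levels = seq_len(nnode))),
       ids = branch_ids(po))
}

# 4 x npat tip partial-likelihood matrices; missing states give all-ones.
tip_partials <- function(pat) {
  npat <- ncol(pat)
  lapply(seq_len(nrow(pat)), function(i) {
    m <- matrix(0, 4, npat)
    s <- pat[i, ]
    obs <- s > 0L
    m[cbind(s[obs], which(obs))] <- 1
    m[, !obs] <- 1
    m
  })
}

# Postorder (conditional-on-subtree) partials. Returns per-node partials D,
# per-edge messages msg[[child]] = P(t) %*% D[[child]].
down_partials <- function(st, tipL, lengths, model) {
  D <- vector("list", st$nnode)
  msg <- vector("list", st$nnode)
  for (k in seq_len(nrow(st$edge))) {
    p <- st$edge[k, 1]; v <- st$edge[k, 2]
    Dv <- if (v <= st$ntip) tipL[[v]] else D[[v]]
    msg[[v]] <- tp(model, lengths[k]) %*% Dv
    D[[p]] <- if (is.null(D[[p]])) msg[[v]] else D[[p]] * msg[[v]]
  }
  D[seq_len(st$ntip)] <- tipL
  list(D = D, msg = msg)
}

# Preorder partials: U[[v]] gives, per state of v's parent, the likelihood of
# all data outside v's subtree (including the root prior).
up_partials <- function(st, dp, lengths, model) {
  U <- vector("list", st$nnode)
  ones <- matrix(1, 4, ncol(dp$D[[st$root]]))
  for (k in rev(seq_len(nrow(st$edge)))) {
    p <- st$edge[k, 1]; v <- st$edge[k, 2]
    sib <- ones
    for (s in st$children[[p]]) if (s != v) sib <- sib * dp$msg[[s]]
    U[[v]] <- if (p == st$root) {
      model$pi * sib
    } else {
      crossprod(tp(model, lengths[st$edge_of_child[p]]), U[[p]]) * sib
    }
  }
  U
}

# Log-likelihood from root partials.
root_loglik <- function(st, dp, model, w) {
  R <- dp$D[[st$root]]
  sum(w * log(.colSums(R * model$pi, 4L, ncol(R))))
}

# Log-likelihood as a function of a single edge length, all else cached:
# L_site = sum_i U_v(i) [P(t) D_v]_i.
edge_loglik <- function(Uv, Dv, model, t, w) {
  sum(w * log(.colSums(Uv * (tp(model, t) %*% Dv), 4L, ncol(Dv))))
}

# Factory for the same objective with the spectral trick: with
# P(t) = sum_k exp(lambda_k t) a_k b_k', the per-site likelihood becomes
# sum_k exp(lambda_k t) C[k, s] for a coefficient matrix C fixed per edge,
# so each evaluation costs O(4 * npat) with no matrix products.
edge_loglik_fn <- function(Uv, Dv, model, w) {
  C <- crossprod(model$evec_left, Uv) * (model$evec_right %*% Dv)
  lam <- model$evalues
  np <- ncol(C)
  function(t) {
    s <- .colSums(exp(lam * t) * C, 4L, np)
    if (min(s) <= 0) s <- pmax(s, 1e-300)
    sum(w * log(s))
  }
}

# Safeguarded Newton maximisation of the single-edge objective, using the
# analytic gradient/curvature available from the spectral coefficients.
# Backtracks on non-improving steps; checks the t = 0 boundary.
newton_branch <- function(Uv, Dv, model, w, t0, max_len) {
  C <- crossprod(model$evec_left, Uv) * (model$evec_right %*% Dv)
  lam <- model$evalues
  np <- ncol(C)
  eval3 <- function(t) {
    M <- exp(lam * t) * C
    s0 <- .colSums(M, 4L, np)
    if (min(s0) <= 0) s0 <- pmax(s0, 1e-300)
    r1 <- .colSums(lam * M, 4L, np) / s0
    list(ll = sum(w * log(s0)), g = sum(w * r1),
         h = sum(w * (.colSums(lam * lam * M, 4L, np) / s0 - r1 * r1)))
  }
  t <- min(max(t0, 1e-6), max_len)
  ev <- eval3(t)
  for (it in 1:15) {
    step <- if (ev$h < 0) -ev$g / ev$h else sign(ev$g) * max(0.5 * t, 0.01)
    tn <- min(max(t + step, 0), max_len)
    if (abs(tn - t) < 1e-9) break
    evn <- eval3(tn)
    tries <- 0
    while (evn$ll < ev$ll - 1e-12 && tries < 8) {
      tn <- (t + tn) / 2
      evn <- eval3(tn)
      tries <- tries + 1
    }
    if (evn$ll < ev$ll - 1e-12) break
    t <- tn
    ev <- evn
    if (abs(ev$g) * max(t, 0.01) < 1e-8 * (abs(ev$ll) + 1)) break
  }
  if (t < 1e-4) {
    e0 <- eval3(0)
    if (e0$ll >= ev$ll) return(list(t = 0, ll = e0$ll))
  }
  list(t = t, ll = ev$ll)
}

# ---- exported likelihood ----------------------------------------------------

#' Felsenstein pruning log-likelihood
#'
#' Computes the log-likelihood of an alignment on a fixed tree under a
#' reversible substitution model, optionally rescaling individual branches.
#' Gap and ambiguity characters are treated as missing data (partial
#' likelihood 1 for all states). Tips of the tree absent from the alignment
#' are marginalised over, keeping the full topology.
#'
#' @param alignment Character matrix (rows = species, named), `DNAbin`, or
#'   named character vector of aligned sequences over `A,C,G,T,-,N`.
#' @param tree Rooted `phylo` with branch lengths in expected
#'   substitutions/site.
#' @param model A [subst_model][hky_model].
#' @param branch_scales Optional named numeric vector (names from
#'   [branch_ids()]); each named branch length is multiplied by its scale.
#'   Scales must be positive.
#' @return The log-likelihood (scalar).
#' @examples
#' tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05);")
#' aln <- rbind(a = c("A", "C"), b = c("A", "C"),
#'              c = c("A", "T"), d = c("A", "T"))
#' prune_loglik(aln, tr, jc_model())
#' @export
prune_loglik <- function(alignment, tree, model = jc_model(),
                         branch_scales = NULL) {
  states <- aln_states(alignment)
  if (ncol(states) == 0L) stop("empty alignment")
  extra <- setdiff(rownames(states), tree$tip.label)
  if (length(extra))
    stop("alignment tips absent from tree: ", paste(extra, collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  st <- tree_struct(tree)
  lengths <- st$tree$edge.length
  if (!is.null(branch_scales)) {
    if (is.null(names(branch_scales)) ||
        !all(names(branch_scales) %in% st$ids))
      stop("branch_scales must be named by valid branch ids")
    if (any(branch_scales <= 0)) stop("branch scales must be positive")
    lengths[match(names(branch_scales), st$ids)] <-
      lengths[match(names(branch_scales), st$ids)] * branch_scales
  }
  full <- matrix(0L, st$ntip, ncol(states),
                 dimnames = list(st$tree$tip.label, NULL))
  have <- intersect(st$tree$tip.label, rownames(states))
  full[have, ] <- states[have, ]
  pd <- compress_patterns(full)
  tipL <- tip_partials(pd$pat)
  dp <- down_partials(st, tipL, lengths, model)
  root_loglik(st, dp, model, pd$w)
}
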