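# Shared fixtures and independent oracles.

# Fixed 4-taxon tree used across likelihood tests.
tiny_tree <- function() {
  ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.3,d:0.15):0.07);")
}

# Random rooted tree with uniform branch lengths.
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, 0.4)
  tr
}

random_alignment <- function(tips, nsites, seed,
                             alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  matrix(sample(alphabet, length(tips) * nsites, replace = TRUE),
         nrow = length(tips), dimnames = list(tips, NULL))
}

# Independent HKY rate matrix + matrix-exponential transition probabilities
# (no shared code with the package's spectral implementation).
oracle_hky_Q <- function(pi, kappa) {
  Q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  ti <- list(c(1, 3), c(3, 1), c(2, 4), c(4, 2))  # A<->G, C<->T
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    is_ti <- any(vapply(ti, function(p) p[1] == i && p[2] == j, TRUE))
    Q[i, j] <- (if (is_ti) kappa else 1) * pi[j]
  }
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

oracle_pmat <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# Exhaustive-enumeration likelihood: sums over every assignment of states to
# internal nodes. Missing tip states (gap/N) contribute a factor of 1 (the
# transition row sums to 1 when marginalised).
oracle_loglik <- function(aln, tree, pi, kappa) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  Q <- oracle_hky_Q(pi, kappa)
  P <- lapply(tree$edge.length, function(t) oracle_pmat(Q, t))
  states <- match(toupper(aln[tree$tip.label, , drop = FALSE]),
                  c("A", "C", "G", "T"))
  states <- matrix(ifelse(is.na(states), 0L, states), nrow = ntip)
  internal <- (ntip + 1):nnode
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  root <- ntip + 1L
  total <- 0
  for (s in seq_len(ncol(states))) {
    col <- states[, s]
    Lsum <- 0
    for (g in seq_len(nrow(grid))) {
      ass <- integer(nnode)
      ass[internal] <- grid[g, ]
      pr <- pi[ass[root]]
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
        sv <- if (v <= ntip) col[v] else ass[v]
        if (sv == 0L) next
        pr <- pr * P[[e]][ass[p], sv]
      }
      Lsum <- Lsum + pr
    }
    total <- total + log(Lsum)
  }
  total
}

# Brute-force CNE -> gene assignment: all-pairs midpoint containment.
oracle_assign <- function(cnes, domains) {
  lapply(seq_len(nrow(cnes)), function(i) {
    mid <- (cnes$start[i] + cnes$end[i]) %/% 2
    hit <- domains$chrom == cnes$chrom[i] &
      domains$e_start <= mid & mid < domains$e_end
    sort(domains$gene_id[hit])
  })
}

# Two-sided conditional exact test by hypergeometric enumeration.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  sum(probs[probs <= stats::dhyper(a, r1, r2, c1) * (1 + 1e-7)])
}

# Deterministic binary mask containing one filled ellipse.
ellipse_mask <- function(a, b, theta = 0, pad = 6) {
  r <- ceiling(max(a, b)) + pad
  size <- 2 * r + 1
  px <- cnedrift:::fill_ellipse(r + 1, r + 1, a, b, theta, c(size, size))
  m <- matrix(0L, size, size)
  m[px] <- 1L
  m
}
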