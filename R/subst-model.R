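#' Nucleotide substitution models
#'
#' Constructors for the reversible substitution models used throughout the
#' package: Jukes-Cantor (`jc_model()`) and HKY (`hky_model()`). The rate
#' matrix is normalised to one expected substitution per unit time, so branch
#' lengths are in expected substitutions per site.
#'
#' @param pi Numeric vector of length 4, equilibrium base frequencies in the
#'   order A, C, G, T. Must be positive and is renormalised to sum to 1.
#' @param kappa Transition/transversion rate ratio (kappa = 1 reduces HKY to
#'   F81; with equal frequencies, to JC).
#' @return An object of class `subst_model` with elements `pi`, `kappa`, `Q`
#'   and a spectral decomposition used to compute transition probabilities.
#' @examples
#' m <- hky_model(pi = c(0.3, 0.2, 0.2, 0.3), kappa = 3)
#' P <- transition_prob(m, 0.1)
#' rowSums(P)  # each row sums to 1
#' @export
hky_model <- function(pi = rep(0.25, 4), kappa = 2) {
  stopifnot(length(pi) == 4, all(is.finite(pi)), all(pi > 0),
            is.finite(kappa), kappa > 0)
  pi <- pi / sum(pi)
  names(pi) <- DNA_STATES
  Q <- matrix(0, 4, 4, dimnames = list(DNA_STATES, DNA_STATES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    Q[i, j] <- if (is_transition(i, j)) kappa * pi[j] else pi[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))  # expected substitutions per unit time
  Q <- Q / mu
  structure(
    c(list(name = if (kappa == 1 && all(abs(pi - 0.25) < 1e-12)) "JC" else "HKY",
           pi = pi, kappa = kappa, Q = Q),
      spectral_decompose(Q, pi)),
    class = "subst_model")
}

#' @rdname hky_model
#' @export
jc_model <- function() hky_model(pi = rep(0.25, 4), kappa = 1)

DNA_STATES <- c("A", "C", "G", "T")

# A<->G and C<->T are transitions (indices 1-3 and 2-4)
is_transition <- function(i, j) (i + j) %in% c(4L, 6L) && abs(i - j) == 2L

# Reversible Q is similar to a symmetric matrix: S = D Q D^-1, D = diag(sqrt(pi)).
# P(t) = A diag(exp(lambda t)) B with A = D^-1 V, B = t(V) D.
spectral_decompose <- function(Q, pi) {
  d <- sqrt(pi)
  S <- (Q * rep(d, times = 4)) / rep(d, each = 4)  # d_i Q_ij / d_j
  S <- (S + t(S)) / 2  # symmetrise numerically
  es <- eigen(S, symmetric = TRUE)
  list(evec_left = es$vectors / d,         # A = D^-1 V   (rows scaled)
       evec_right = t(es$vectors) * rep(d, each = 4),  # B = t(V) D
       evalues = es$values)
}

#' Transition probability matrix
#'
#' @param model A `subst_model`.
#' @param t Branch length in expected substitutions per site (>= 0).
#' @return 4x4 matrix `P` with `P[i, j] = P(state j at time t | state i at 0)`.
#' @export
transition_prob <- function(model, t) {
  stopifnot(inherits(model, "subst_model"), is.finite(t), t >= 0)
  P <- tp(model, t)
  P / rowSums(P)
}

# validation-free kernel for hot loops; negative round-off clamped to 0
tp <- function(model, t) {
  P <- model$evec_left %*% (exp(model$evalues * t) * model$evec_right)
  P[P < 0] <- 0
  P
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s substitution model (kappa = %.4g)\n", x$name, x$kappa))
  cat("  pi:", paste(sprintf("%s=%.3f", DNA_STATES, x$pi), collapse = " "), "\n")
  invisible(x)
}
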