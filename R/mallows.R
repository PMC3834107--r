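# Mallows distribution over causal orderings, with Kendall-tau distance,
# the closed-form normalizing constant, and exact repeated-insertion
# sampling. Used as the symmetric Metropolis-Hastings proposal.

#' Dispersion parameter of the Mallows model
#'
#' The proposal sharpness is parameterized by a temperature `eta > 0`
#' through `phi = exp(-1/eta)`, `phi` in (0, 1]. Under `P(O*) ~ phi^d(O*, O)`,
#' `phi = 1` gives the uniform distribution over orderings and `phi -> 0`
#' concentrates on the reference ordering.
#'
#' @param eta positive temperature.
#' @return The dispersion `phi = exp(-1/eta)`.
#' @export
mallows_phi <- function(eta) {
  stopifnot(is.numeric(eta), all(eta > 0))
  exp(-1 / eta)
}

#' Kendall tau distance between two orderings
#'
#' Counts the unordered pairs of nodes ranked in opposite relative order by
#' the two permutations; symmetric, between 0 and `p(p-1)/2`.
#'
#' @param a,b integer permutations of `1..p` (position -> node).
#' @return Non-negative integer count of pairwise disagreements.
#' @export
kendall_distance <- function(a, b) {
  p <- length(a)
  if (length(b) != p) stop("orderings must have the same length")
  a <- check_ordering(a, p)
  b <- check_ordering(b, p)
  ra <- rb <- integer(p)
  ra[a] <- seq_len(p) # rank (position) of each node
  rb[b] <- seq_len(p)
  d <- 0L
  for (u in seq_len(p - 1L)) {
    v <- (u + 1L):p
    d <- d + sum((ra[u] - ra[v]) * (rb[u] - rb[v]) < 0)
  }
  d
}

# log normalizing constant of the Kendall-Mallows model:
# Z(phi, p) = prod_{i=1..p} (1 + phi + ... + phi^{i-1}).
mallows_log_z <- function(phi, p) {
  i <- seq_len(p)
  if (phi == 1) return(sum(log(i)))
  sum(log1p(-phi^i) - log1p(-phi))
}

#' Mallows log-density of an ordering
#'
#' `log P(o | ref, phi) = d(o, ref) log(phi) - log Z(phi, p)` with the
#' closed-form Kendall normalizer `Z(phi, p) = prod_i (1 + phi + ... +
#' phi^{i-1})`. The density is symmetric in `(o, ref)`, which is what
#' cancels the proposal terms in the Metropolis-Hastings ratio.
#'
#' @param o,ref integer permutations of `1..p`.
#' @param eta temperature (used as `phi = exp(-1/eta)` unless `phi` given).
#' @param phi dispersion in (0, 1]; overrides `eta`.
#' @return The log-density.
#' @export
mallows_log_density <- function(o, ref, eta = NULL, phi = NULL) {
  phi <- phi %||% mallows_phi(eta)
  stopifnot(phi > 0, phi <= 1)
  p <- length(ref)
  kendall_distance(o, ref) * log(phi) - mallows_log_z(phi, p)
}

#' Sample an ordering from the Mallows model (repeated insertion)
#'
#' Draws exactly from `P(O*) ~ phi^d(O*, ref)` by the repeated insertion
#' model: items 1..p are inserted one at a time, item `i` going to
#' position `j <= i` with probability `phi^{i-j} / (1 + phi + ... +
#' phi^{i-1})`, independently across `i`; the resulting permutation is
#' composed with `ref`.
#'
#' @param ref integer permutation of `1..p`, the centre of the proposal.
#' @param eta temperature (`phi = exp(-1/eta)`) unless `phi` given.
#' @param phi dispersion in (0, 1]; overrides `eta`.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return An integer permutation of `1..p`.
#' @export
sample_mallows <- function(ref, eta = NULL, phi = NULL, seed = NULL) {
  phi <- phi %||% mallows_phi(eta)
  stopifnot(phi > 0, phi <= 1)
  p <- length(ref)
  ref <- check_ordering(ref, p)
  with_seed(seed, ref[rim_draw(p, phi)])
}

# One repeated-insertion draw centered at the identity: returns a
# permutation v (position -> item) with P(v) ~ phi^{inversions(v)}.
rim_draw <- function(p, phi) {
  v <- integer(p)
  v[1L] <- 1L
  if (p == 1L) return(v)
  pw <- phi^(seq_len(p) - 1L) # phi^0 .. phi^{p-1}
  for (i in 2:p) {
    # insertion position j in 1..i with weight phi^{i-j}
    j <- sample.int(i, 1L, prob = pw[i:1])
    if (j < i) v[(j + 1L):i] <- v[j:(i - 1L)]
    v[j] <- i
  }
  v
}

# Closed-form mean Kendall distance under Mallows(phi), used in tests:
# E[d] = sum_{i=1..p} ( phi/(1-phi) - i phi^i / (1-phi^i) ), phi < 1.
mallows_mean_distance <- function(phi, p) {
  if (phi == 1) return(p * (p - 1) / 4)
  i <- seq_len(p)
  sum(phi / (1 - phi) - i * phi^i / (1 - phi^i))
}
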