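#' Parameters of a causal Gaussian Bayesian network
#'
#' Bundles the weighted DAG with the residual means and standard deviations
#' of the structural equations
#' `X_j = m_j + sum_{i in pa(j)} w_{i,j} X_i + eps_j`,
#' `eps_j ~ N(0, sigma_j^2)` independent across genes and samples.
#'
#' @param dag a [weighted_dag()].
#' @param m numeric vector of residual means (length `p`, recycled from a
#'   scalar).
#' @param sigma numeric vector of residual standard deviations (length `p`,
#'   recycled from a scalar); entries must be strictly positive. `NA`
#'   entries are allowed to mark components a fit could not identify.
#' @return An object of class `"gbn_params"`.
#' @export
gbn_params <- function(dag, m = 0, sigma = 1) {
  stopifnot(inherits(dag, "weighted_dag"))
  p <- dag$p
  if (length(m) == 1L) m <- rep(m, p)
  if (length(sigma) == 1L) sigma <- rep(sigma, p)
  if (length(m) != p || length(sigma) != p)
    stop("'m' and 'sigma' must have length ", p)
  if (any(sigma <= 0, na.rm = TRUE)) stop("'sigma' must be strictly positive")
  names(m) <- names(sigma) <- dag$labels
  structure(list(dag = dag, m = as.numeric(m), sigma = as.numeric(sigma),
                 p = p, labels = dag$labels),
            class = "gbn_params")
}

#' @export
print.gbn_params <- function(x, ...) {
  cat("Gaussian Bayesian network parameters:", x$p, "genes,",
      sum(x$dag$W != 0), "edges\n")
  print(data.frame(gene = x$labels, m = x$m, sigma = x$sigma,
                   row.names = NULL))
  invisible(x)
}

new_gaussian_law <- function(mu, cov, labels) {
  names(mu) <- labels
  dimnames(cov) <- list(labels, labels)
  structure(list(mu = mu, cov = cov, labels = labels), class = "gaussian_law")
}

#' @export
print.gaussian_law <- function(x, ...) {
  cat("Multivariate Gaussian law on", length(x$mu), "genes\nMeans:\n")
  print(x$mu)
  cat("Covariance:\n")
  print(x$cov)
  invisible(x)
}

#' Exact joint law of the network without interventions
#'
#' With row-vector convention `X = mL + eps L`, `L = (I - W)^{-1}`, the
#' joint distribution is Gaussian with mean `mL` and covariance
#' `L' diag(sigma^2) L`.
#'
#' @param params a [gbn_params()].
#' @return An object of class `"gaussian_law"` with elements `mu` and `cov`.
#' @export
observational_law <- function(params) {
  stopifnot(inherits(params, "gbn_params"))
  L <- total_effects(params$dag)
  mu <- as.numeric(params$m %*% L)
  cov <- crossprod(L * params$sigma) # t(L) diag(sigma^2) L, row-scaled
  new_gaussian_law(mu, cov, params$labels)
}

#' Exact joint law under an intervention do(X_J = x_J)
#'
#' Clamping the genes in `targets` severs their incoming edges (columns of
#' `W` zeroed, giving `W_J`) and fixes them deterministically at their clamp
#' values. The remaining genes are jointly Gaussian with mean
#' `nu_J(x_J) L_J` and covariance `sum_{j not in J} sigma_j^2 L_J' e_j' e_j L_J`,
#' where `nu_J` replaces `m_j` by the clamp value for clamped genes and
#' `L_J = (I - W_J)^{-1}`. Rows and columns of the covariance for clamped
#' genes are identically zero.
#'
#' @param params a [gbn_params()].
#' @param targets character vector of gene labels (or integer indices) to
#'   clamp; empty means no intervention.
#' @param values clamp values, recycled (default 0, a knock-out).
#' @return An object of class `"gaussian_law"` for the full gene vector.
#' @export
intervention_law <- function(params, targets = character(), values = 0) {
  stopifnot(inherits(params, "gbn_params"))
  J <- resolve_targets(targets, params$labels)
  if (!length(J)) return(observational_law(params))
  values <- rep_len(as.numeric(values), length(J))
  WJ <- params$dag$W
  WJ[, J] <- 0
  LJ <- total_effects(weighted_dag(WJ, params$labels))
  nu <- params$m
  nu[J] <- values
  mu <- as.numeric(nu %*% LJ)
  s <- params$sigma
  s[J] <- 0
  cov <- crossprod(LJ * s)
  new_gaussian_law(mu, cov, params$labels)
}

# Map labels or indices to validated integer indices.
resolve_targets <- function(targets, labels) {
  if (is.null(targets) || !length(targets)) return(integer())
  if (is.numeric(targets)) {
    J <- as.integer(targets)
    if (any(J < 1L | J > length(labels))) stop("clamp index out of range")
  } else {
    J <- match(as.character(targets), labels)
    if (anyNA(J))
      stop("unknown gene in intervention: ",
           paste(targets[is.na(J)], collapse = ", "))
  }
  if (anyDuplicated(J)) stop("duplicated clamp target")
  J
}

#' Draw edge weights for a network skeleton
#'
#' Nonzero weights are sampled uniformly from `(-1, -0.25) U (0.25, 1)`:
#' magnitude uniform on (0.25, 1), sign an independent fair coin. This is
#' the weight distribution of the simulation benchmark.
#'
#' @param skeleton a [weighted_dag()] whose nonzero pattern defines the
#'   edge set (stored weights are ignored).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return A [weighted_dag()] with freshly drawn weights.
#' @export
random_weights <- function(skeleton, seed = NULL) {
  stopifnot(inherits(skeleton, "weighted_dag"))
  idx <- which(skeleton$W != 0)
  with_seed(seed, {
    mag <- stats::runif(length(idx), 0.25, 1)
    sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
    W <- skeleton$W
    W[idx] <- mag * sgn
    weighted_dag(W, skeleton$labels)
  })
}

#' Simulate expression data from a Gaussian Bayesian network
#'
#' Each sample is generated by traversing the genes in a topological order
#' of the DAG: genes clamped by the sample's intervention are set to their
#' clamp values; every other gene is drawn from its structural equation
#' `X_j = m_j + sum_{i in pa(j)} w_{i,j} X_i + eps_j` with independent
#' Gaussian residuals.
#'
#' @param params a [gbn_params()].
#' @param design an [intervention_design()]; its length sets the number of
#'   samples.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return A [gbn_data()] expression dataset (samples x genes).
#' @export
sample_gbn <- function(params, design, seed = NULL) {
  stopifnot(inherits(params, "gbn_params"), inherits(design, "intervention_design"))
  p <- params$p
  N <- length(design$targets)
  W <- params$dag$W
  ord <- topological_order(W)
  Jk <- lapply(design$targets, resolve_targets, labels = params$labels)
  with_seed(seed, {
    X <- matrix(0, N, p, dimnames = list(design$sample_id, params$labels))
    for (j in ord) {
      X[, j] <- params$m[j] + X %*% W[, j] + stats::rnorm(N, 0, params$sigma[j])
      for (k in seq_len(N)) {
        hit <- match(j, Jk[[k]])
        if (!is.na(hit)) X[k, j] <- design$values[[k]][hit]
      }
    }
    gbn_data(X, design, labels = params$labels)
  })
}
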