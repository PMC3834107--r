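# Shared fixtures: small DAGs, permutation enumeration, an independent
# numerical maximizer of the intervention log-likelihood, and a cache for
# the scaled-down benchmark used by the acceptance tests.

# 3-gene chain with a shortcut edge 1 -> 3.
chain3 <- function(a = 0.8, b = -0.5, cc = 0.3) {
  W <- matrix(0, 3, 3)
  W[1, 2] <- a
  W[2, 3] <- b
  W[1, 3] <- cc
  weighted_dag(W)
}

# Random acyclic weight matrix with relabelled nodes (uses current RNG).
rand_dag <- function(p, density = 0.4) {
  W <- matrix(0, p, p)
  iu <- which(upper.tri(W))
  on <- iu[stats::runif(length(iu)) < density]
  W[on] <- stats::runif(length(on), 0.25, 1) *
    sample(c(-1, 1), length(on), replace = TRUE)
  perm <- sample.int(p)
  weighted_dag(W[perm, perm])
}

# All permutations of 1..p as rows.
all_perms <- function(p) {
  if (p == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(p - 1L)
  do.call(rbind, lapply(seq_len(p), function(k)
    cbind(k, sub + (sub >= k))))
}

# Independent oracle: maximize the intervention log-likelihood of the
# complete DAG consistent with `ord` by a generic numerical optimizer
# (never touches the closed-form profile solution).
optim_loglik <- function(dat, ord) {
  p <- dat$p
  pairs <- do.call(rbind, lapply(2:p, function(t)
    cbind(ord[seq_len(t - 1)], ord[t])))
  npar <- 2 * p + nrow(pairs)
  unpack <- function(theta) {
    W <- matrix(0, p, p)
    W[pairs] <- theta[2 * p + seq_len(nrow(pairs))]
    gbn_params(weighted_dag(W, dat$labels), theta[seq_len(p)],
               exp(theta[p + seq_len(p)]))
  }
  nll <- function(theta) -gbn_loglik(unpack(theta), dat)
  start <- c(colMeans(dat$X), log(apply(dat$X, 2, stats::sd)),
             numeric(nrow(pairs)))
  o <- stats::optim(start, nll, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-15))
  o <- stats::optim(o$par, nll, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-15))
  -o$value
}

# Brute-force AUROC: exhaustive positive-vs-negative pair comparison with
# half credit for ties.
auroc_brute <- function(score, positive) {
  ps <- score[positive]
  ns <- score[!positive]
  cmp <- outer(ps, ns, ">") + 0.5 * outer(ps, ns, "==")
  mean(cmp)
}

# The scaled-down simulation benchmark shared by the acceptance tests:
# 20 datasets per setting, sigma = 0.1, 20000-iteration chains.
.acc_cache <- new.env(parent = emptyenv())

acceptance_benchmark <- function(setting) {
  key <- paste0("bench_", setting)
  if (is.null(.acc_cache[[key]]))
    .acc_cache[[key]] <- run_benchmark(setting, sigma = 0.1, n_datasets = 20,
                                       n_iter = 20000, burn_in = 2000,
                                       thin = 50, eta = "auto", seed = 1)
  .acc_cache[[key]]
}

bench_mean <- function(setting, mat, crit) {
  s <- acceptance_benchmark(setting)$summary
  s$mean[s$matrix == mat & s$criterion == crit]
}
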