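# A small helper: simulate a mixed observational/KO dataset from a known
# network on the current RNG stream.
sim_instance <- function(dag, m = 0.5, sigma = 0.3, n_wt = 6, ko = list()) {
  par0 <- gbn_params(dag, m = m, sigma = sigma)
  des <- intervention_design(c(replicate(n_wt, character(), simplify = FALSE), ko))
  list(params = par0, data = sample_gbn(par0, des))
}

test_that("single-gene likelihood reduces to the univariate Gaussian", {
  set.seed(1)
  x <- stats::rnorm(12, 1.5, 0.7)
  dat <- gbn_data(matrix(x, ncol = 1, dimnames = list(NULL, "N1")))
  par0 <- gbn_params(weighted_dag(matrix(0, 1, 1)), m = 1.2, sigma = 0.6)
  expect_equal(gbn_loglik(par0, dat),
               sum(stats::dnorm(x, 1.2, 0.6, log = TRUE)))
})

test_that("likelihood equals the joint-Gaussian density route", {
  # independent oracle: for each sample evaluate the multivariate normal
  # density of the non-clamped genes under the exact (intervention) law
  set.seed(2)
  g <- rand_dag(4, density = 0.6)
  inst <- sim_instance(g, n_wt = 5, ko = list("N1", c("N2", "N4")))
  par0 <- inst$params
  dat <- inst$data
  mvn_ll <- 0
  for (k in seq_len(dat$N)) {
    tg <- dat$design$targets[[k]]
    law <- intervention_law(par0, tg, dat$design$values[[k]])
    idx <- setdiff(seq_len(dat$p), match(tg, dat$labels))
    S <- law$cov[idx, idx]
    d <- dat$X[k, idx] - law$mu[idx]
    ch <- chol(S)
    mvn_ll <- mvn_ll - length(idx) / 2 * log(2 * pi) - sum(log(diag(ch))) -
      0.5 * sum(backsolve(ch, d, transpose = TRUE)^2)
  }
  expect_equal(gbn_loglik(par0, dat), mvn_ll, tolerance = 1e-10)
})

test_that("profile estimates zero the likelihood gradient", {
  set.seed(3)
  g <- rand_dag(4, density = 0.6)
  inst <- sim_instance(g, n_wt = 10, ko = list("N1", "N3"))
  dat <- inst$data
  ord <- ordercause:::topological_order(inst$params$dag$W)
  fit <- fit_ordering(dat, ord)
  par_hat <- fit$params
  h <- 1e-5
  # means
  for (j in 1:4) {
    pp <- pm <- par_hat
    pp$m[j] <- pp$m[j] + h
    pm$m[j] <- pm$m[j] - h
    expect_lt(abs(gbn_loglik(pp, dat) - gbn_loglik(pm, dat)) / (2 * h), 1e-6)
  }
  # sigmas
  for (j in 1:4) {
    pp <- pm <- par_hat
    pp$sigma[j] <- pp$sigma[j] + h
    pm$sigma[j] <- pm$sigma[j] - h
    grad <- (gbn_loglik(pp, dat) - gbn_loglik(pm, dat)) / (2 * h)
    expect_lt(abs(grad), 1e-5)
  }
  # every free weight of the complete DAG consistent with the ordering
  for (t in 2:4) for (s in seq_len(t - 1)) {
    i <- ord[s]; j <- ord[t]
    pp <- pm <- par_hat
    pp$dag$W[i, j] <- pp$dag$W[i, j] + h
    pm$dag$W[i, j] <- pm$dag$W[i, j] - h
    expect_lt(abs(gbn_loglik(pp, dat) - gbn_loglik(pm, dat)) / (2 * h), 1e-5)
  }
})

test_that("profile means and sigmas have their closed forms when W = 0", {
  set.seed(4)
  X <- matrix(stats::rnorm(40, 2, 0.5), 10, 4,
              dimnames = list(NULL, paste0("N", 1:4)))
  dat <- gbn_data(X)
  W0 <- matrix(0, 4, 4)
  expect_equal(unname(profile_mean(dat, W0)), unname(colMeans(X)))
  expect_equal(unname(profile_sigma(dat, W0)),
               unname(apply(X, 2, function(v) sqrt(mean((v - mean(v))^2)))))
})

test_that("samples clamping gene j never affect gene j's own estimates", {
  set.seed(5)
  g <- rand_dag(4, density = 0.6)
  inst <- sim_instance(g, n_wt = 12)
  dat <- inst$data
  ord <- ordercause:::topological_order(g$W)
  fit0 <- fit_ordering(dat, ord)
  j <- ord[3]
  lab <- dat$labels[j]
  # append two knock-outs of gene j (arbitrary clamp values)
  extra <- sample_gbn(inst$params,
                      intervention_design(list(lab, lab), values = list(0, 1.3)))
  dat2 <- gbn_data(rbind(dat$X, extra$X),
                   intervention_design(c(dat$design$targets, extra$design$targets),
                                       c(dat$design$values, extra$design$values)))
  fit2 <- fit_ordering(dat2, ord)
  expect_equal(fit2$params$m[j], fit0$params$m[j], tolerance = 1e-12)
  expect_equal(fit2$params$sigma[j], fit0$params$sigma[j], tolerance = 1e-12)
  expect_equal(fit2$params$dag$W[, j], fit0$params$dag$W[, j], tolerance = 1e-12)
})

test_that("rank-deficient parent systems are flagged and solved minimum-norm", {
  set.seed(6)
  x1 <- stats::rnorm(10)
  x3 <- 0.8 * x1 + stats::rnorm(10, 0, 0.1)
  X <- cbind(N1 = x1, N2 = x1, N3 = x3) # duplicated candidate parents
  dat <- gbn_data(X)
  pw <- profile_weights(dat, c(1, 2, 3))
  expect_true(nrow(pw$degenerate) >= 1)
  expect_true(3 %in% pw$degenerate[, "target"])
  # minimum-norm splits the coefficient equally over the duplicated parents
  expect_equal(pw$W["N1", "N3"], pw$W["N2", "N3"], tolerance = 1e-8)
  expect_true(is.finite(fit_ordering(dat, c(1, 2, 3))$loglik))
})

test_that("a gene clamped in every sample contributes nothing and is flagged NA", {
  set.seed(7)
  g <- chain3()
  par0 <- gbn_params(g, m = 0.5, sigma = 0.3)
  des <- intervention_design(replicate(8, "N1", simplify = FALSE))
  dat <- sample_gbn(par0, des)
  fit <- fit_ordering(dat, 1:3)
  expect_true(is.na(fit$params$m["N1"]))
  expect_true(is.na(fit$params$sigma["N1"]))
  # N1 varies not at all but still acts as a (constant) predictor column;
  # the fit stays finite and the other genes are estimated
  expect_true(is.finite(fit$loglik))
  expect_false(anyNA(fit$params$m[2:3]))
})

test_that("profile fit matches a generic numerical optimizer", {
  set.seed(8)
  g <- rand_dag(3, density = 0.7)
  inst <- sim_instance(g, n_wt = 28, ko = list("N2", "N3"))
  ord <- sample.int(3)
  fit <- fit_ordering(inst$data, ord)
  ll_opt <- optim_loglik(inst$data, ord)
  expect_lt(abs(fit$loglik - ll_opt), 1e-5)
  expect_gte(fit$loglik, ll_opt - 1e-6) # profile optimum can only be better
})

test_that("observational likelihood is invariant to the ordering", {
  set.seed(9)
  g <- rand_dag(4, density = 0.6)
  inst <- sim_instance(g, n_wt = 15)
  perms <- all_perms(4)
  lls <- apply(perms, 1, function(o) fit_ordering(inst$data, o)$loglik)
  expect_lt(max(lls) - min(lls), 1e-8)
})

test_that("growing the candidate parent set never hurts the fit", {
  set.seed(10)
  g <- rand_dag(4, density = 0.6)
  inst <- sim_instance(g, n_wt = 10, ko = list("N1"))
  # gene at the last position with 2 vs 3 preceding genes
  s_small <- profile_sigma(inst$data, profile_weights(inst$data, c(1, 2, 4, 3))$W)
  s_big <- profile_sigma(inst$data, profile_weights(inst$data, c(1, 2, 3, 4))$W)
  expect_lte(s_big["N4"], s_small["N4"] + 1e-12)
})

test_that("the C++ and R profile log-likelihoods agree", {
  set.seed(11)
  for (i in 1:10) {
    g <- rand_dag(sample(3:6, 1), density = 0.5)
    ko <- lapply(sample(g$labels, 2), identity)
    inst <- sim_instance(g, n_wt = 8, ko = ko)
    suff <- ordercause:::suffstats(inst$data)
    ord <- sample.int(g$p)
    ll_r <- ordercause:::fit_ordering_suff(suff, ord)$loglik
    ll_c <- ordercause:::profile_loglik_cpp(suff$C, suff$Nj, as.integer(ord), 1e-8)
    expect_equal(ll_r, ll_c, tolerance = 1e-8)
  }
})
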