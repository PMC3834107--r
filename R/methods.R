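# S3 methods for fitted "ordercause" objects.

#' @export
print.ordercause <- function(x, ...) {
  cat("Causal ordering MCMC fit (", x$mode, " proposals)\n", sep = "")
  cat(sprintf("  data       : %d samples x %d genes\n",
              x$data$N, x$data$p))
  if (x$mode == "mallows")
    cat(sprintf("  eta        : %g (phi = %.4f)\n", x$eta, x$phi))
  cat(sprintf("  schedule   : %d iterations, burn-in %d, thin %d (%d kept)\n",
              x$n_iter, x$burn_in, x$thin, nrow(x$kept_orders)))
  cat(sprintf("  acceptance : %.1f%%\n", 100 * x$acceptance_rate))
  cat(sprintf("  best loglik: %.4f\n", x$best$loglik))
  cat("  best order : ", paste(x$labels[x$best$order], collapse = " < "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.ordercause <- function(object, ...) {
  eff <- estimate_effects(object, "best")
  uniq <- nrow(unique(object$kept_orders))
  out <- list(fit = object, effects = eff, n_unique_kept = uniq)
  class(out) <- "summary.ordercause"
  out
}

#' @export
print.summary.ordercause <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  unique kept orderings: %d of %d\n", x$n_unique_kept,
              nrow(x$fit$kept_orders)))
  cat("\nEstimated direct effects (best ordering), entries |w| > 0.1:\n")
  W <- x$effects$direct
  W[abs(W) <= 0.1] <- 0
  print(round(W, 3))
  invisible(x)
}

#' @export
coef.ordercause <- function(object, type = c("direct", "total"), ...) {
  type <- match.arg(type)
  eff <- estimate_effects(object, "best")
  eff[[type]]
}

#' @export
logLik.ordercause <- function(object, ...) logLik(object$best)

#' Heat map of the posterior node-by-position frequencies
#'
#' Displays the proportion of kept orderings that place each gene at each
#' position, the standard summary of the sampled ordering posterior.
#'
#' @param x a fitted [ordercause()] object.
#' @param ... passed to [graphics::image()].
#' @export
plot.ordercause <- function(x, ...) {
  M <- x$position_matrix
  p <- nrow(M)
  graphics::image(seq_len(p), seq_len(p), t(M[rev(seq_len(p)), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "position in causal ordering", ylab = "",
                  axes = FALSE, ...)
  graphics::axis(1, at = seq_len(p))
  graphics::axis(2, at = seq_len(p), labels = rev(rownames(M)), las = 1)
  graphics::box()
  invisible(x)
}

#' Expected expression under an intervention, from a fitted model
#'
#' Returns the mean vector (and covariance) of the fitted network under
#' `do(X_targets = values)`; with no targets, the observational law.
#'
#' @param object a fitted [ordercause()] object.
#' @param targets genes to clamp (labels or indices); empty for none.
#' @param values clamp values, recycled (default 0).
#' @param ... unused.
#' @return A `"gaussian_law"` object (elements `mu`, `cov`).
#' @export
predict.ordercause <- function(object, targets = character(), values = 0, ...) {
  intervention_law(object$best$params, targets, values)
}

#' Simulate expression data from a fitted model
#'
#' @param object a fitted [ordercause()] object.
#' @param nsim number of datasets to draw.
#' @param seed optional seed; the caller's RNG state is restored.
#' @param design an [intervention_design()]; defaults to the design of the
#'   fitted data.
#' @param ... unused.
#' @return A list of `nsim` [gbn_data()] datasets (a single dataset when
#'   `nsim = 1`).
#' @export
simulate.ordercause <- function(object, nsim = 1, seed = NULL,
                                design = NULL, ...) {
  design <- design %||% object$data$design
  out <- with_seed(seed, replicate(nsim,
    sample_gbn(object$best$params, design), simplify = FALSE))
  if (nsim == 1) out[[1]] else out
}

#' @export
residuals.ordercause <- function(object, ...) {
  par <- object$best$params
  dat <- object$data
  R <- dat$X - dat$X %*% par$dag$W -
    matrix(par$m, dat$N, dat$p, byrow = TRUE)
  R[clamp_matrix(dat)] <- NA_real_ # clamped entries have no residual
  R
}
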