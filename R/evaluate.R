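# Scoring of estimated effect matrices against a known network, and the
# simulation benchmark driver.

# Rank-statistic AUROC with midranks for ties: the Mann-Whitney
# probability that a positive outranks a negative (ties half credit).
auroc_rank <- function(score, positive) {
  np <- sum(positive)
  nn <- sum(!positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(score) # midranks
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# Area under the precision-recall curve by step interpolation, grouping
# tied scores at a single threshold.
auprc_step <- function(score, positive) {
  np <- sum(positive)
  if (np == 0L || all(positive)) return(NA_real_)
  o <- order(score, decreasing = TRUE)
  s <- score[o]
  y <- positive[o]
  grp <- cumsum(!duplicated(s)) # threshold groups (ties together)
  tp <- cumsum(y)
  n_at <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE) # last index of each group
  tp <- tp[last]
  n_at <- n_at[last]
  prec <- tp / n_at
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Score an estimated effect matrix against the truth
#'
#' Compares off-diagonal entries of an estimated total or direct effect
#' matrix with the true one by the four benchmark criteria: AUROC and
#' AUPRC for detection (positives are the nonzero true effects, ranking
#' score the absolute estimate), Spearman rank correlation of the signed
#' entries (midranks for ties), and mean squared error of the signed
#' entries.
#'
#' @param truth true `p x p` effect matrix (from a known network, e.g.
#'   [total_effects()] or [direct_effects()]).
#' @param estimate estimated matrix of the same shape (signed).
#' @param ranking optional matrix of ranking scores for AUROC/AUPRC;
#'   defaults to `abs(estimate)`.
#' @param include_diagonal score the diagonal entries too (default
#'   `FALSE`: the diagonal of `L` is identically 1 and of `W` identically
#'   0, carrying no information).
#' @return An object of class `"gbn_score"`: `auroc`, `auprc`,
#'   `spearman`, `mse`, `n_positives`, `n_negatives`.
#' @export
score_effects <- function(truth, estimate, ranking = NULL,
                          include_diagonal = FALSE) {
  truth <- as.matrix(truth)
  estimate <- as.matrix(estimate)
  if (!all(dim(truth) == dim(estimate)))
    stop("'truth' and 'estimate' must have the same shape")
  ranking <- ranking %||% abs(estimate)
  keep <- if (include_diagonal) rep(TRUE, length(truth)) else
    !diag(nrow(truth))
  tv <- truth[keep]
  ev <- estimate[keep]
  rv <- ranking[keep]
  positive <- tv != 0
  structure(list(
    auroc = auroc_rank(rv, positive),
    auprc = auprc_step(rv, positive),
    spearman = suppressWarnings(stats::cor(tv, ev, method = "spearman")),
    mse = mean((tv - ev)^2),
    n_positives = sum(positive),
    n_negatives = sum(!positive)), class = "gbn_score")
}

#' @export
print.gbn_score <- function(x, ...) {
  cat(sprintf(
    "AUROC %.3f | AUPRC %.3f | Spearman %.3f | MSE %.4f (%d pos / %d neg)\n",
    x$auroc, x$auprc, x$spearman, x$mse, x$n_positives, x$n_negatives))
  invisible(x)
}

#' Run the simulation benchmark for one design setting
#'
#' Replicates the knock-out benchmark: for each of `n_datasets`
#' replicates, draw fresh edge weights on the network skeleton (uniform on
#' `(-1,-0.25) U (0.25, 1)`), simulate the chosen intervention design with
#' residual means 0.5 and standard deviation `sigma`, run the
#' Metropolis-Hastings chain (uniform proposals for the observational
#' design, Mallows otherwise), estimate total and direct effect matrices,
#' and score them against the generating network. The Mallows temperature
#' is tuned on the first replicate and shared across replicates of the
#' setting.
#'
#' @param setting design name, see [benchmark_design()].
#' @param sigma residual standard deviation of the simulated genes.
#' @param n_datasets number of replicate datasets.
#' @param dag network skeleton, a [weighted_dag()]; default the bundled
#'   10-gene network.
#' @param n_iter,burn_in,thin chain schedule per dataset.
#' @param eta Mallows temperature or `"auto"` (tuned on the first
#'   replicate, then shared).
#' @param estimator `"best"`, `"posterior_mean"`, or `NULL` to pick
#'   `"best"` for Mallows runs and `"posterior_mean"` for the uniform
#'   (observational) baseline.
#' @param mean_expr residual mean of every gene (benchmark value 0.5).
#' @param drop_hidden_ko passed to [mask_hidden()] for the hidden-gene
#'   design.
#' @param seed integer seed; replicate `d` runs on stream `seed + d - 1`.
#' @param verbose print one line per dataset.
#' @return An object of class `"gbn_benchmark"`: `scores` (one row per
#'   dataset and matrix type), `summary` (mean and SD per criterion),
#'   `position` (kept-ordering position frequencies averaged over
#'   datasets), `eta`, and the run `manifest`.
#' @export
run_benchmark <- function(setting = c("observational", "mixed", "partial_ko",
                                      "multiple_ko", "multiple_ko_hidden"),
                          sigma = 0.1, n_datasets = 20,
                          dag = example_network(),
                          n_iter = 20000, burn_in = 2000, thin = 50,
                          eta = "auto", estimator = NULL, mean_expr = 0.5,
                          drop_hidden_ko = FALSE, seed = 1, verbose = FALSE) {
  setting <- match.arg(setting)
  mode <- if (setting == "observational") "uniform" else "mallows"
  estimator <- estimator %||%
    (if (mode == "uniform") "posterior_mean" else "best")
  rows <- list()
  pos_sum <- 0
  eta_used <- if (mode == "uniform") NA_real_ else eta
  hidden_used <- character()
  for (d in seq_len(n_datasets)) {
    row <- with_seed(seed + d - 1, {
      truth_dag <- random_weights(dag)
      bd <- benchmark_design(setting, labels = dag$labels)
      params <- gbn_params(truth_dag, m = mean_expr, sigma = sigma)
      dat <- sample_gbn(params, bd$design)
      truth_L <- total_effects(truth_dag)
      truth_W <- direct_effects(truth_dag)
      if (length(bd$hidden)) {
        dat <- mask_hidden(dat, bd$hidden, drop_hidden_ko = drop_hidden_ko)
        keep <- dat$labels
        truth_L <- truth_L[keep, keep]
        truth_W <- truth_W[keep, keep]
        hidden_used <- union(hidden_used, bd$hidden)
      }
      if (mode == "mallows" && identical(eta_used, "auto"))
        eta_used <- as.numeric(tune_eta(dat))
      fit <- ordercause(dat, mode = mode, n_iter = n_iter, burn_in = burn_in,
                        thin = thin,
                        eta = if (mode == "mallows") eta_used else "auto")
      eff <- estimate_effects(fit, estimator)
      sc_tot <- score_effects(truth_L, eff$total, ranking = eff$total_abs)
      sc_dir <- score_effects(truth_W, eff$direct, ranking = eff$direct_abs)
      pos_sum <- pos_sum + fit$position_matrix
      list(
        data.frame(dataset = d, matrix = "total", auroc = sc_tot$auroc,
                   auprc = sc_tot$auprc, spearman = sc_tot$spearman,
                   mse = sc_tot$mse, acceptance = fit$acceptance_rate),
        data.frame(dataset = d, matrix = "direct", auroc = sc_dir$auroc,
                   auprc = sc_dir$auprc, spearman = sc_dir$spearman,
                   mse = sc_dir$mse, acceptance = fit$acceptance_rate))
    })
    rows <- c(rows, row)
    if (verbose)
      message(sprintf("[%s] dataset %d/%d: AUROC(total) %.3f",
                      setting, d, n_datasets, row[[1]]$auroc))
  }
  scores <- do.call(rbind, rows)
  crit <- c("auroc", "auprc", "spearman", "mse")
  summ <- do.call(rbind, lapply(split(scores, scores$matrix), function(df) {
    data.frame(matrix = df$matrix[1], criterion = crit,
               mean = vapply(df[crit], mean, numeric(1)),
               sd = vapply(df[crit], stats::sd, numeric(1)),
               row.names = NULL)
  }))
  rownames(summ) <- NULL
  structure(list(
    setting = setting, sigma = sigma, scores = scores, summary = summ,
    position = pos_sum / n_datasets, eta = eta_used,
    manifest = list(setting = setting, sigma = sigma,
                    n_datasets = n_datasets, n_iter = n_iter,
                    burn_in = burn_in, thin = thin, seed = seed,
                    estimator = estimator, eta = eta_used,
                    hidden = hidden_used)),
    class = "gbn_benchmark")
}

#' @export
print.gbn_benchmark <- function(x, ...) {
  cat(sprintf("Benchmark '%s' (sigma = %g, %d datasets)\n", x$setting,
              x$sigma, max(x$scores$dataset)))
  if (!is.na(x$eta) && x$setting != "observational")
    cat("  Mallows eta:", x$eta, "\n")
  df <- x$summary
  df$mean <- round(df$mean, 3)
  df$sd <- round(df$sd, 3)
  print(df)
  invisible(x)
}

#' Write the run manifest of a benchmark as JSON
#'
#' @param bench a [run_benchmark()] result.
#' @param file output path.
#' @export
write_manifest <- function(bench, file) {
  jsonlite::write_json(bench$manifest, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
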