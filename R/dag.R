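#' Weighted directed acyclic graph
#'
#' Container for the direct-effect matrix of a causal Gaussian Bayesian
#' network. Entry `W[i, j]` is the weight of the edge from gene `i` to gene
#' `j` (0 when the edge is absent). The nonzero pattern must be acyclic;
#' the constructor verifies this by topological sort.
#'
#' @param W square numeric matrix of edge weights, `W[i, j]` the direct
#'   effect of gene `i` on gene `j`.
#' @param labels character vector of gene names; defaults to the column
#'   names of `W` or `N1..Np`.
#' @return An object of class `"weighted_dag"` with elements `p`, `labels`
#'   and `W`.
#' @examples
#' W <- matrix(0, 3, 3); W[1, 2] <- 0.8; W[2, 3] <- -0.5
#' g <- weighted_dag(W)
#' total_effects(g)
#' @export
weighted_dag <- function(W, labels = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("'W' must be square")
  if (!is.numeric(W) || anyNA(W)) stop("'W' must be numeric with no NAs")
  p <- nrow(W)
  labels <- labels %||% colnames(W) %||% paste0("N", seq_len(p))
  if (length(labels) != p || anyDuplicated(labels))
    stop("'labels' must be ", p, " unique names")
  labels <- as.character(labels)
  dimnames(W) <- list(labels, labels)
  topological_order(W) # errors on cycles
  structure(list(p = p, labels = labels, W = W), class = "weighted_dag")
}

#' @export
print.weighted_dag <- function(x, ...) {
  ne <- sum(x$W != 0)
  cat("Weighted DAG:", x$p, "nodes,", ne, "edges\n")
  if (ne) {
    ij <- which(x$W != 0, arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    ed <- data.frame(source = x$labels[ij[, 1]], target = x$labels[ij[, 2]],
                     weight = x$W[ij], row.names = NULL)
    print(utils::head(ed, 25L))
    if (ne > 25L) cat("... (", ne - 25L, " more edges)\n", sep = "")
  }
  invisible(x)
}

# Kahn's algorithm; returns a topological order of the nonzero pattern of W
# or stops if the graph is cyclic.
topological_order <- function(W) {
  if (inherits(W, "weighted_dag")) W <- W$W
  p <- nrow(W)
  A <- W != 0
  indeg <- colSums(A)
  done <- logical(p)
  out <- integer(p)
  for (t in seq_len(p)) {
    cand <- which(!done & indeg <= 0)
    if (!length(cand))
      stop("the weight matrix contains a directed cycle; no causal ordering exists")
    v <- cand[1L]
    out[t] <- v
    done[v] <- TRUE
    indeg <- indeg - A[v, ]
  }
  out
}

# Logical reachability matrix: [i, j] TRUE when i is a (proper) ancestor of j.
ancestor_matrix <- function(dag) {
  A <- dag$W != 0
  R <- A
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  dimnames(R) <- dimnames(dag$W)
  R
}

#' Total causal effect matrix
#'
#' Computes `L = (I - W)^{-1} = I + W + ... + W^{p-1}` using the nilpotence
#' of an acyclic weight matrix. Entry `(i, j)`, `i != j`, is the total causal
#' effect of gene `i` on gene `j`: the derivative of `E[X_j | do(X_i = x)]`
#' with respect to `x`. The diagonal is 1, and the entry is exactly 0
#' whenever `i` is not an ancestor of `j`.
#'
#' The matrix is accumulated by a Horner scheme on the power series (which
#' preserves exact structural zeros) and cross-checked against a triangular
#' solve in a topological ordering.
#'
#' @param dag a [weighted_dag()].
#' @return A `p x p` labelled matrix of total effects.
#' @export
total_effects <- function(dag) {
  stopifnot(inherits(dag, "weighted_dag"))
  W <- dag$W
  p <- dag$p
  I <- diag(p)
  L <- I
  if (p > 1) for (k in seq_len(p - 1L)) L <- I + W %*% L
  # independent route: triangular solve after permuting to topological order
  ord <- topological_order(W)
  Lt <- diag(p)
  if (p > 1) {
    U <- diag(p) - W[ord, ord]
    Lt[ord, ord] <- backsolve(U, diag(p))
  }
  if (max(abs(L - Lt)) > 1e-6 * max(1, max(abs(L))))
    warning("triangular solve and power series disagree; using the power series")
  dimnames(L) <- dimnames(W)
  L
}

#' Direct causal effect matrix
#'
#' The direct effect of gene `i` on gene `j` holding `j`'s other parents
#' fixed is the edge weight `w_{i,j}` itself; this accessor returns the
#' weight matrix for use in evaluation code.
#'
#' @param dag a [weighted_dag()].
#' @return The `p x p` weight matrix.
#' @export
direct_effects <- function(dag) {
  stopifnot(inherits(dag, "weighted_dag"))
  dag$W
}

#' Read / write a DAG as an edge-list TSV
#'
#' The exchange format is a tab-separated file with a header line and three
#' columns `source`, `target`, `weight`.
#'
#' @param file path to the TSV file.
#' @param labels optional character vector fixing the node set and order;
#'   defaults to the labels in order of first appearance in the file.
#' @return `read_dag()` returns a [weighted_dag()]; `write_dag()` returns
#'   `file` invisibly.
#' @export
read_dag <- function(file, labels = NULL) {
  ed <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("source", "target", "weight")
  if (!all(need %in% names(ed)))
    stop("DAG file must have columns: ", paste(need, collapse = ", "))
  labels <- labels %||% unique(c(rbind(ed$source, ed$target)))
  miss <- setdiff(unique(c(ed$source, ed$target)), labels)
  if (length(miss)) stop("edge labels not in 'labels': ", paste(miss, collapse = ", "))
  p <- length(labels)
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  W[cbind(match(ed$source, labels), match(ed$target, labels))] <- ed$weight
  weighted_dag(W, labels)
}

#' @rdname read_dag
#' @param dag a [weighted_dag()] to write.
#' @export
write_dag <- function(dag, file) {
  stopifnot(inherits(dag, "weighted_dag"))
  ij <- which(dag$W != 0, arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  ed <- data.frame(source = dag$labels[ij[, 1]], target = dag$labels[ij[, 2]],
                   weight = sprintf("%.17g", dag$W[ij]))
  utils::write.table(ed, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write an effect (or weight) matrix as labelled CSV
#'
#' @param m labelled square matrix (e.g. from [total_effects()]).
#' @param file output path.
#' @export
write_effects <- function(m, file) {
  utils::write.csv(as.data.frame(m), file, row.names = TRUE)
  invisible(file)
}

#' The bundled 10-gene benchmark network
#'
#' Returns the synthetic 10-node, 21-edge DAG shipped with the package
#' (`inst/extdata/dag10_synthetic.tsv`) that anchors the simulation
#' benchmark. It is a constructed stand-in network, not taken from any
#' published study: it reproduces the structural features the benchmark
#' relies on (10 genes `N1..N10`, 21 edges, gene N6 a root that can occupy
#' only the first three positions of a causal ordering, gene N3 a global
#' sink that every other gene affects, so it can only be placed last).
#' The stored weights are one fixed example parameterization; benchmark
#' runs redraw weights per dataset with [random_weights()].
#'
#' @return A [weighted_dag()] with labels `N1..N10`.
#' @export
example_network <- function() {
  f <- system.file("extdata", "dag10_synthetic.tsv", package = "ordercause",
                   mustWork = TRUE)
  read_dag(f, labels = paste0("N", 1:10))
}
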