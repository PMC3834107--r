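#' Intervention design
#'
#' Records, for each sample, the (possibly empty) set of genes clamped by
#' intervention and their clamp values. An empty clamp set denotes a
#' wild-type (observational) sample.
#'
#' @param targets list with one element per sample: a character vector of
#'   clamped gene labels (may be empty).
#' @param values clamp values: a single number recycled to every clamp
#'   (default 0, knock-out), or a list matching `targets` elementwise.
#' @param n shorthand: if `targets` is missing, `n` empty (wild-type)
#'   entries are created.
#' @param sample_id optional character vector of sample names.
#' @return An object of class `"intervention_design"`.
#' @examples
#' # 2 wild-types and a double knock-out of N1 and N4
#' intervention_design(list(character(), character(), c("N1", "N4")))
#' @export
intervention_design <- function(targets = NULL, values = 0, n = NULL,
                                sample_id = NULL) {
  if (is.null(targets)) {
    stopifnot(!is.null(n))
    targets <- replicate(n, character(), simplify = FALSE)
  }
  stopifnot(is.list(targets))
  targets <- lapply(targets, as.character)
  N <- length(targets)
  if (!is.list(values)) {
    values <- lapply(targets, function(tg) rep_len(as.numeric(values), length(tg)))
  } else {
    stopifnot(length(values) == N)
    values <- Map(function(tg, v) rep_len(as.numeric(v), length(tg)),
                  targets, values)
  }
  for (k in seq_len(N))
    if (anyDuplicated(targets[[k]]))
      stop("sample ", k, " clamps a gene more than once")
  sample_id <- sample_id %||% paste0("s", seq_len(N))
  stopifnot(length(sample_id) == N)
  structure(list(targets = targets, values = values,
                 sample_id = as.character(sample_id)),
            class = "intervention_design")
}

#' @export
print.intervention_design <- function(x, ...) {
  N <- length(x$targets)
  nwt <- sum(lengths(x$targets) == 0L)
  cat("Intervention design:", N, "samples (", nwt, "wild-type,",
      N - nwt, "intervened )\n")
  invisible(x)
}

#' @export
length.intervention_design <- function(x) length(x$targets)

#' Expression dataset with its intervention design
#'
#' Pairs an `N x p` expression matrix (samples in rows, genes in columns)
#' with the [intervention_design()] describing which genes were clamped in
#' each sample.
#'
#' @param X numeric matrix, samples x genes, with gene labels as column
#'   names (or supplied through `labels`).
#' @param design an [intervention_design()] with one entry per row of `X`;
#'   `NULL` means all samples are observational.
#' @param labels gene labels; defaults to `colnames(X)`.
#' @return An object of class `"gbn_data"`.
#' @export
gbn_data <- function(X, design = NULL, labels = NULL) {
  X <- as.matrix(X)
  labels <- labels %||% colnames(X) %||% paste0("N", seq_len(ncol(X)))
  stopifnot(length(labels) == ncol(X))
  colnames(X) <- labels
  design <- design %||% intervention_design(n = nrow(X))
  stopifnot(inherits(design, "intervention_design"),
            length(design) == nrow(X))
  for (tg in design$targets) resolve_targets(tg, labels)
  if (is.null(rownames(X))) rownames(X) <- design$sample_id
  structure(list(X = X, design = design, labels = as.character(labels),
                 N = nrow(X), p = ncol(X)),
            class = "gbn_data")
}

#' @export
print.gbn_data <- function(x, ...) {
  cat("Expression dataset:", x$N, "samples x", x$p, "genes\n")
  print(x$design)
  invisible(x)
}

#' @export
dim.gbn_data <- function(x) dim(x$X)

# N x p logical matrix: TRUE where the gene is clamped in the sample.
clamp_matrix <- function(data) {
  M <- matrix(FALSE, data$N, data$p,
              dimnames = list(rownames(data$X), data$labels))
  for (k in seq_len(data$N)) {
    J <- resolve_targets(data$design$targets[[k]], data$labels)
    M[k, J] <- TRUE
  }
  M
}

#' Benchmark intervention designs for the 10-gene network
#'
#' The five designs of the simulation benchmark, for genes labelled
#' `N1..N10` (clamp value 0 throughout):
#' \describe{
#'   \item{observational}{20 wild-type replicates, no interventions.}
#'   \item{mixed}{10 wild-types and one knock-out per gene.}
#'   \item{partial_ko}{15 wild-types and knock-outs of the five genes
#'     N1, N4, N6, N7, N9.}
#'   \item{multiple_ko}{10 wild-types, one knock-out per gene, and the five
#'     double knock-outs \{N1,N5\}, \{N1,N6\}, \{N4,N7\}, \{N6,N9\},
#'     \{N7,N10\}.}
#'   \item{multiple_ko_hidden}{the multiple_ko design, plus three gene
#'     labels drawn at random to be masked from the simulated data
#'     afterwards (see [mask_hidden()]).}
#' }
#'
#' @param name one of the five design names above.
#' @param seed optional seed used only to draw the hidden genes.
#' @param labels gene labels of the target network (default `N1..N10`).
#' @return A list with elements `design` (an [intervention_design()]) and
#'   `hidden` (character vector of genes to mask; empty except for
#'   `multiple_ko_hidden`).
#' @export
benchmark_design <- function(name = c("observational", "mixed", "partial_ko",
                                      "multiple_ko", "multiple_ko_hidden"),
                             seed = NULL, labels = paste0("N", 1:10)) {
  name <- match.arg(name)
  wt <- function(n) replicate(n, character(), simplify = FALSE)
  single <- lapply(labels, function(g) g)
  doubles <- list(c("N1", "N5"), c("N1", "N6"), c("N4", "N7"),
                  c("N6", "N9"), c("N7", "N10"))
  targets <- switch(name,
    observational      = wt(20),
    mixed              = c(wt(10), single),
    partial_ko         = c(wt(15), lapply(c("N1", "N4", "N6", "N7", "N9"),
                                          function(g) g)),
    multiple_ko        = c(wt(10), single, doubles),
    multiple_ko_hidden = c(wt(10), single, doubles))
  if (name %in% c("partial_ko", "multiple_ko", "multiple_ko_hidden")) {
    used <- unique(unlist(targets))
    if (!all(used %in% labels))
      stop("design '", name, "' requires genes ",
           paste(setdiff(used, labels), collapse = ", "))
  }
  hidden <- character()
  if (name == "multiple_ko_hidden")
    hidden <- with_seed(seed, sample(labels, 3L))
  list(design = intervention_design(targets), hidden = hidden)
}

#' Mask hidden genes from a dataset
#'
#' Removes the columns of the hidden genes and strips them from every
#' sample's clamp set: an intervention on a hidden gene still happened in
#' the data-generating process but is unobserved, so a sample that only
#' knocked out hidden genes becomes an apparently observational sample of
#' the remaining genes. With `drop_hidden_ko = TRUE` such samples are
#' dropped instead of kept.
#'
#' @param data a [gbn_data()].
#' @param hidden character vector of gene labels to hide (a strict subset
#'   of the genes).
#' @param drop_hidden_ko drop samples whose clamp set intersects `hidden`
#'   (default `FALSE`: keep them with the hidden clamps removed).
#' @return A [gbn_data()] on the observed genes.
#' @export
mask_hidden <- function(data, hidden, drop_hidden_ko = FALSE) {
  stopifnot(inherits(data, "gbn_data"))
  hidden <- as.character(hidden)
  if (!length(hidden)) return(data)
  resolve_targets(hidden, data$labels)
  keep <- setdiff(data$labels, hidden)
  if (!length(keep)) stop("cannot mask every gene")
  rows <- seq_len(data$N)
  if (drop_hidden_ko)
    rows <- rows[!vapply(data$design$targets,
                         function(tg) any(tg %in% hidden), logical(1))]
  targets <- lapply(data$design$targets[rows], function(tg) setdiff(tg, hidden))
  values <- Map(function(tg, v) v[!(tg %in% hidden)],
                data$design$targets[rows], data$design$values[rows])
  design <- intervention_design(targets, values,
                                sample_id = data$design$sample_id[rows])
  gbn_data(data$X[rows, keep, drop = FALSE], design, labels = keep)
}

#' Read / write expression matrices and design files
#'
#' The expression format is a delimited table with a header of gene names
#' and one row per sample (row names = sample ids). The design format has
#' columns `sample_id`, `clamped_genes` (comma-separated labels or `-` for
#' none) and `clamp_values` (comma-separated reals or `-`).
#'
#' @param data a [gbn_data()].
#' @param file path; `design_file` optional companion design path.
#' @param sep field separator, tab by default (use `","` for CSV).
#' @return `read_gbn_data()` returns a [gbn_data()]; writers return their
#'   path invisibly.
#' @export
write_gbn_data <- function(data, file, design_file = NULL, sep = "\t") {
  stopifnot(inherits(data, "gbn_data"))
  # %.17g keeps doubles exact across a write/read round trip
  Xc <- matrix(sprintf("%.17g", data$X), nrow(data$X),
               dimnames = dimnames(data$X))
  utils::write.table(Xc, file, sep = sep, quote = FALSE,
                     row.names = TRUE, col.names = NA)
  if (!is.null(design_file)) write_design(data$design, design_file)
  invisible(file)
}

#' @rdname write_gbn_data
#' @export
read_gbn_data <- function(file, design_file = NULL, sep = "\t") {
  X <- as.matrix(utils::read.table(file, sep = sep, header = TRUE,
                                   row.names = 1, check.names = FALSE))
  design <- if (!is.null(design_file)) read_design(design_file) else NULL
  gbn_data(X, design)
}

#' @rdname write_gbn_data
#' @param design an [intervention_design()].
#' @export
write_design <- function(design, file) {
  stopifnot(inherits(design, "intervention_design"))
  fmt <- function(x) if (length(x)) paste(x, collapse = ",") else "-"
  df <- data.frame(
    sample_id = design$sample_id,
    clamped_genes = vapply(design$targets, fmt, character(1)),
    clamp_values = vapply(design$values, function(v) fmt(sprintf("%.17g", v)),
                          character(1)))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_gbn_data
#' @export
read_design <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = "character")
  parse1 <- function(s, num) {
    if (s == "-" || !nzchar(s)) return(if (num) numeric() else character())
    out <- strsplit(s, ",", fixed = TRUE)[[1]]
    if (num) as.numeric(out) else out
  }
  targets <- lapply(df$clamped_genes, parse1, num = FALSE)
  values <- lapply(df$clamp_values, parse1, num = TRUE)
  intervention_design(targets, values, sample_id = df$sample_id)
}
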