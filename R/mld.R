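#' Construct a multi-label dataset
#'
#' Bundles a numeric feature matrix (samples x genes, typically fitted
#' R_max values) with a binary label matrix (samples x findings) and the
#' associated identifiers.  All downstream fitting and evaluation
#' functions in this package consume this container.
#'
#' @param features numeric matrix, one row per sample, one column per gene.
#' @param labels binary (0/1) matrix with the same number of rows as
#'   `features`, one column per pathological finding.
#' @param gene_ids character vector of column names for `features`;
#'   defaults to existing column names or `gene1..geneD`.
#' @param label_names character vector of column names for `labels`.
#' @param sample_ids character vector of unique sample (compound)
#'   identifiers.
#' @param provenance character vector per sample, each `"original"` or
#'   `"synthetic"`.
#'
#' @return An object of class `"mld"`: a list with elements `features`,
#'   `labels`, `gene_ids`, `label_names`, `sample_ids`, `provenance`.
#' @examples
#' x <- matrix(rnorm(20), 5, 4)
#' y <- matrix(rbinom(10, 1, 0.4), 5, 2)
#' d <- mld(x, y)
#' d
#' @export
mld <- function(features, labels, gene_ids = NULL, label_names = NULL,
                sample_ids = NULL, provenance = NULL) {
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  storage.mode(features) <- "double"
  storage.mode(labels) <- "double"
  n <- nrow(features)
  if (is.null(gene_ids)) {
    gene_ids <- colnames(features)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(features)))
  }
  if (is.null(label_names)) {
    label_names <- colnames(labels)
    if (is.null(label_names)) label_names <- paste0("label", seq_len(ncol(labels)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(features)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  }
  if (is.null(provenance)) provenance <- rep("original", n)
  obj <- structure(
    list(features = features, labels = labels,
         gene_ids = as.character(gene_ids),
         label_names = as.character(label_names),
         sample_ids = as.character(sample_ids),
         provenance = as.character(provenance)),
    class = "mld")
  validate_mld(obj)
  colnames(obj$features) <- obj$gene_ids
  colnames(obj$labels) <- obj$label_names
  rownames(obj$features) <- rownames(obj$labels) <- obj$sample_ids
  obj
}

#' Validate a multi-label dataset
#'
#' Checks the structural invariants of an [mld] object: consistent
#' dimensions, strictly binary labels, finite features and unique sample
#' identifiers.  Called by the constructor; exported so that readers and
#' generators can assert validity on their outputs.
#'
#' @param x an object of class `"mld"`.
#' @return `x`, invisibly; an error is thrown on violation.
#' @export
validate_mld <- function(x) {
  stopifnot(inherits(x, "mld"))
  n <- nrow(x$features)
  if (n < 1L || ncol(x$features) < 1L || ncol(x$labels) < 1L)
    stop("mld requires n >= 1 samples, >= 1 gene and >= 1 label")
  if (nrow(x$labels) != n)
    stop("features and labels disagree on the number of samples")
  if (length(x$gene_ids) != ncol(x$features))
    stop("gene_ids length does not match the feature columns")
  if (length(x$label_names) != ncol(x$labels))
    stop("label_names length does not match the label columns")
  if (length(x$sample_ids) != n || anyDuplicated(x$sample_ids))
    stop("sample_ids must be unique and one per sample")
  if (length(x$provenance) != n ||
      !all(x$provenance %in% c("original", "synthetic")))
    stop("provenance must be 'original' or 'synthetic' per sample")
  if (!all(is.finite(x$features)))
    stop("features must be finite")
  if (!all(x$labels %in% c(0, 1)))
    stop("labels must be strictly in {0, 1}")
  invisible(x)
}

#' @export
print.mld <- function(x, ...) {
  cat(sprintf("Multi-label dataset: %d samples x %d genes, %d labels\n",
              nrow(x$features), ncol(x$features), ncol(x$labels)))
  cat(sprintf("  synthetic samples: %d / %d\n",
              sum(x$provenance == "synthetic"), nrow(x$features)))
  pos <- colSums(x$labels)
  cat("  positives per label: ", paste(pos, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.mld <- function(x) c(nrow(x$features), ncol(x$features), ncol(x$labels))

# subset rows of an mld, keeping all metadata in register
mld_subset <- function(x, idx) {
  mld(x$features[idx, , drop = FALSE], x$labels[idx, , drop = FALSE],
      gene_ids = x$gene_ids, label_names = x$label_names,
      sample_ids = x$sample_ids[idx], provenance = x$provenance[idx])
}
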