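#' Read a long-format expression table
#'
#' Reads a CSV with columns `compound_id, dose_level, time_h, gene_id,
#' value`, one row per (compound, dose level, gene) expression
#' measurement, the dialect written by [write_expression_table()] and by
#' the synthetic generator.
#'
#' @param path path to a CSV file.
#' @return A data.frame of validated records with columns `compound_id`
#'   (character), `dose_level` (one of `"low"`, `"middle"`, `"high"`),
#'   `time_h` (numeric), `gene_id` (character), `value` (numeric).  Row
#'   order is preserved.
#' @seealso [write_expression_table()], [build_rmax_features()]
#' @export
read_expression_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "character"))
  required <- c("compound_id", "dose_level", "time_h", "gene_id", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("expression table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[required]
  bad_dose <- setdiff(unique(df$dose_level), dose_levels())
  if (length(bad_dose))
    stop("unknown dose level token(s): ", paste(bad_dose, collapse = ", "),
         " (expected low, middle, high)")
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(!is.finite(val))
  if (length(bad))
    stop("non-numeric or non-finite expression value at row ", bad[1L],
         " ('", df$value[bad[1L]], "')")
  df$value <- val
  key <- paste(df$compound_id, df$dose_level, df$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[which(duplicated(key))[1L], ]
    stop("duplicated record for compound ", d$compound_id, ", gene ",
         d$gene_id, ", dose ", d$dose_level)
  }
  # every (compound, gene) must carry all three dose levels
  cg <- paste(df$compound_id, df$gene_id, sep = "\r")
  n_dose <- tapply(df$dose_level, cg, function(z) length(unique(z)))
  gap <- names(n_dose)[n_dose < 3L][1L]
  if (!is.na(gap)) {
    parts <- strsplit(gap, "\r", fixed = TRUE)[[1L]]
    stop("missing dose level(s) for compound ", parts[1L], ", gene ",
         parts[2L])
  }
  df
}

#' Write a long-format expression table
#'
#' @param records data.frame as returned by [read_expression_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binary pathology label table
#'
#' Reads a CSV with a `sample_id` column followed by one 0/1 column per
#' pathological finding.
#'
#' @param path path to a CSV file.
#' @param expected_label_names optional character vector; when given, the
#'   file must contain exactly these label columns (any order) and the
#'   returned matrix is reordered to match.
#' @return A binary matrix (samples x labels) with `sample_id` row names.
#' @export
read_label_table <- function(path, expected_label_names = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("label table must have a sample_id column")
  ids <- as.character(df$sample_id)
  lab <- as.matrix(df[setdiff(names(df), "sample_id")])
  if (!is.numeric(lab) || !all(lab %in% c(0, 1)))
    stop("label cells must be 0 or 1")
  if (!is.null(expected_label_names)) {
    unknown <- setdiff(colnames(lab), expected_label_names)
    if (length(unknown))
      stop("unknown label column(s): ", paste(unknown, collapse = ", "))
    absent <- setdiff(expected_label_names, colnames(lab))
    if (length(absent))
      stop("missing label column(s): ", paste(absent, collapse = ", "))
    lab <- lab[, expected_label_names, drop = FALSE]
  }
  rownames(lab) <- ids
  lab
}

#' Write a binary pathology label table
#'
#' @param labels binary matrix (samples x labels) with row names used as
#'   sample ids (or `sample_ids` given explicitly).
#' @param path output CSV path.
#' @param sample_ids optional explicit sample identifiers.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- rownames(labels)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(labels)))
  df <- data.frame(sample_id = sample_ids, labels, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a features table (samples x genes)
#'
#' @param path CSV with a `sample_id` column followed by one numeric
#'   column per gene.
#' @return numeric matrix with sample-id row names.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("feature table must have a sample_id column")
  ids <- as.character(df$sample_id)
  x <- as.matrix(df[setdiff(names(df), "sample_id")])
  if (!is.numeric(x) || !all(is.finite(x)))
    stop("feature cells must be finite numbers")
  rownames(x) <- ids
  x
}

#' Write a features table
#'
#' @param features numeric matrix (samples x genes).
#' @param path output CSV path.
#' @param sample_ids optional explicit sample identifiers.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- rownames(features)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(features)))
  df <- data.frame(sample_id = sample_ids, features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

dose_levels <- function() c("low", "middle", "high")

#' Normalize feature matrices
#'
#' Fits a per-gene affine normalization on a training feature matrix and
#' applies the identical map to further matrices (validation/test).  In
#' `"zscore"` mode each training column is centred to mean 0 and scaled
#' to unit standard deviation; columns that are constant on the training
#' split map to 0 with their scale recorded as 1.  `"none"` is the
#' identity.
#'
#' @param train_features numeric matrix used to fit location and scale.
#' @param other_features optional matrix (or list of matrices) to
#'   transform with the training map.
#' @param mode `"zscore"` or `"none"`.
#' @return list with `train` (normalized training matrix), `other`
#'   (normalized other matrix/list, or `NULL`), `center`, `scale`.
#' @examples
#' nf <- normalize_features(matrix(1:6, 3, 2))
#' colMeans(nf$train)
#' @export
normalize_features <- function(train_features, other_features = NULL,
                               mode = c("zscore", "none")) {
  mode <- match.arg(mode)
  train_features <- as.matrix(train_features)
  if (nrow(train_features) < 1L) stop("train_features must be non-empty")
  if (mode == "none") {
    ctr <- rep(0, ncol(train_features))
    scl <- rep(1, ncol(train_features))
  } else {
    ctr <- colMeans(train_features)
    # population standard deviation (standard-scaler convention)
    scl <- sqrt(colMeans(sweep(train_features, 2L, ctr)^2))
    scl[!is.finite(scl) | scl == 0] <- 1  # constant columns -> centred to 0
  }
  apply_map <- function(m) sweep(sweep(as.matrix(m), 2L, ctr), 2L, scl, "/")
  other <- NULL
  if (!is.null(other_features)) {
    other <- if (is.list(other_features)) lapply(other_features, apply_map)
             else apply_map(other_features)
  }
  list(train = apply_map(train_features), other = other,
       center = ctr, scale = scl)
}
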