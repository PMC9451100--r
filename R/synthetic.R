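#' Configuration for the synthetic toxicogenomics generator
#'
#' Describes a synthetic study shaped like an in-vivo toxicogenomics
#' extract: each compound is profiled at three dose levels (low, middle,
#' high) at a single time point, and carries a sparse binary vector of
#' pathological findings.  Informative genes respond to dose along a
#' logistic curve whose plateau is shifted upward by `effect_size` when
#' the gene's associated finding is present, so their fitted maximal
#' response separates positive from negative compounds; the remaining
#' genes are flat apart from measurement jitter and carry no signal.
#' Label dependencies are encoded pairwise: for a pair `(i, j, p)` the
#' conditional probability `P(label_j = 1 | label_i = 1)` is `p`.
#'
#' Default sizes (120 compounds, 200 genes, 20 findings) keep full
#' pipeline runs at desk scale while preserving the structure that
#' matters: three dose levels, sparse correlated labels, strong class
#' imbalance.
#'
#' @param n_compounds number of compounds (one sample per compound).
#' @param n_genes total genes measured.
#' @param informative_fraction fraction of genes carrying dose signal.
#' @param L number of pathological findings (default 20, split 12
#'   liver-style + 8 kidney-style names).
#' @param label_prevalences length-L baseline P(label = 1), in (0, 1);
#'   default a geometric ladder from 0.4 down to 0.02 (strong
#'   imbalance).
#' @param dependency_pairs list of `c(i, j, p)` triples with `i < j`;
#'   `p` is the conditional probability of label j given label i.
#' @param effect_size plateau shift per active associated label, in
#'   expression units.
#' @param base_amplitude dose-response amplitude common to all
#'   informative genes.
#' @param noise_sd measurement noise standard deviation per dose point.
#' @param baseline_range range of per-gene baseline expression.
#' @param time_h exposure time recorded in the long table.
#' @param seed integer RNG seed.
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_compounds = 120L, n_genes = 200L,
                             informative_fraction = 0.25, L = 20L,
                             label_prevalences = NULL,
                             dependency_pairs = list(c(1, 2, 0.8),
                                                     c(3, 5, 0.7)),
                             effect_size = 0.5, base_amplitude = 1,
                             noise_sd = 0.1, baseline_range = c(4, 8),
                             time_h = 24, seed = 1L) {
  if (is.null(label_prevalences))
    label_prevalences <- 0.4 * (0.02 / 0.4)^((seq_len(L) - 1) / max(L - 1, 1))
  if (missing(dependency_pairs))   # default pairs only where they fit L
    dependency_pairs <- Filter(function(p) p[2L] <= L, dependency_pairs)
  if (length(label_prevalences) != L ||
      any(label_prevalences <= 0 | label_prevalences >= 1))
    stop("label_prevalences must be length L, strictly inside (0, 1)")
  if (informative_fraction <= 0 || informative_fraction > 1)
    stop("informative_fraction must be in (0, 1]")
  for (p in dependency_pairs) {
    if (length(p) != 3L || p[1L] >= p[2L] || p[2L] > L)
      stop("dependency pair must be c(i, j, p) with i < j <= L")
    if (p[3L] > 1 || p[3L] < 0)
      stop("infeasible dependency boost: conditional probability ", p[3L],
           " outside [0, 1]")
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 n_genes = as.integer(n_genes),
                 informative_fraction = informative_fraction,
                 L = as.integer(L), label_prevalences = label_prevalences,
                 dependency_pairs = dependency_pairs,
                 effect_size = effect_size, base_amplitude = base_amplitude,
                 noise_sd = noise_sd, baseline_range = baseline_range,
                 time_h = time_h, seed = as.integer(seed)),
            class = "synthetic_config")
}

default_finding_names <- function(L) {
  liver <- c("CI", "EC", "HY", "IM", "NL", "MI", "NE_liv", "HN",
             "KCP", "SCN", "SW", "CV")
  kidney <- c("HC", "LCI", "BC", "CY", "DI", "CD", "NE_kid", "RE")
  all20 <- c(liver, kidney)
  if (L <= length(all20)) all20[seq_len(L)] else
    c(all20, paste0("PF", seq_len(L - length(all20))))
}

#' Simulate a synthetic dose-response toxicogenomics study
#'
#' Draws compound label vectors (with pairwise conditional
#' dependencies), then emits a long-format expression table with one
#' value per (compound, dose level, gene): informative genes follow a
#' logistic dose-response whose maximal response is shifted by
#' `effect_size` when their associated finding is active, noise genes
#' are flat with Gaussian jitter.  All outputs are deterministic given
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `expression` (long data.frame: `compound_id`,
#'   `dose_level`, `time_h`, `gene_id`, `value`), `labels` (binary
#'   matrix compounds x L with compound row names), and `ground_truth`
#'   (list: `informative_genes`, `gene_label` named vector mapping each
#'   informative gene to its finding, `gene_params`, `dependency_pairs`).
#' @examples
#' sim <- simulate_dataset(synthetic_config(n_compounds = 6, n_genes = 10,
#'                                          L = 4, seed = 7))
#' head(sim$expression)
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nC <- config$n_compounds; nG <- config$n_genes; L <- config$L
  compounds <- sprintf("cmp%03d", seq_len(nC))
  genes <- sprintf("g%04d", seq_len(nG))
  findings <- default_finding_names(L)

  # labels, drawn label-by-label so dependencies can condition on earlier ones
  labels <- matrix(0, nC, L, dimnames = list(compounds, findings))
  dep_by_j <- list()
  for (p in config$dependency_pairs)
    dep_by_j[[as.character(p[2L])]] <- p
  for (l in seq_len(L)) {
    pr <- rep(config$label_prevalences[l], nC)
    dep <- dep_by_j[[as.character(l)]]
    if (!is.null(dep)) pr[labels[, dep[1L]] == 1] <- dep[3L]
    labels[, l] <- stats::rbinom(nC, 1L, pr)
  }

  n_inf <- max(1L, round(config$informative_fraction * nG))
  informative <- sort(sample.int(nG, n_inf))
  gene_label <- stats::setNames(
    rep(seq_len(L), length.out = n_inf)[sample.int(n_inf)],
    genes[informative])
  gene_params <- data.frame(
    gene_id = genes,
    informative = seq_len(nG) %in% informative,
    baseline = stats::runif(nG, config$baseline_range[1L],
                            config$baseline_range[2L]),
    ec50 = stats::runif(nG, 1.6, 2.4),
    slope = stats::runif(nG, 3, 6))
  gene_params$label <- NA_character_
  gene_params$label[informative] <- findings[gene_label]

  doses <- c(1, 2, 3)
  value <- numeric(nC * nG * 3L)
  rec_compound <- rep(compounds, each = 3L * nG)
  rec_gene <- rep(rep(genes, each = 3L), times = nC)
  rec_dose <- rep(dose_levels(), times = nC * nG)
  idx <- 1L
  for (ci in seq_len(nC)) {
    for (gi in seq_len(nG)) {
      gp <- gene_params[gi, ]
      if (gp$informative) {
        lab <- gene_label[genes[gi]]
        amp <- config$base_amplitude + config$effect_size * labels[ci, lab]
        mu <- gp$baseline + amp * stats::plogis(gp$slope * (doses - gp$ec50))
      } else {
        mu <- rep(gp$baseline, 3L)
      }
      value[idx:(idx + 2L)] <- mu + stats::rnorm(3L, 0, config$noise_sd)
      idx <- idx + 3L
    }
  }
  expression <- data.frame(compound_id = rec_compound, dose_level = rec_dose,
                           time_h = config$time_h, gene_id = rec_gene,
                           value = value)
  list(expression = expression, labels = labels,
       ground_truth = list(informative_genes = genes[informative],
                           gene_label = gene_label,
                           gene_params = gene_params,
                           dependency_pairs = config$dependency_pairs))
}

#' Assemble an R_max feature dataset from expression records and labels
#'
#' Convenience wrapper: fits the dose-response curves with
#' [build_rmax_features()] and pairs the retained-gene feature matrix
#' with the label table into an [mld()] dataset.
#'
#' @param records long-format expression data.frame.
#' @param labels binary label matrix with compound row names matching
#'   the records' compounds.
#' @param control a [dose_response_control()].
#' @param min_valid_fraction see [build_rmax_features()].
#' @return an [mld()] dataset; attribute `"retained_genes"` lists the
#'   genes that formed valid curves.
#' @export
rmax_dataset <- function(records, labels,
                         control = dose_response_control(),
                         min_valid_fraction = 1) {
  rf <- build_rmax_features(records, control, min_valid_fraction)
  labels <- as.matrix(labels)
  if (is.null(rownames(labels)))
    stop("labels must have compound row names")
  absent <- setdiff(rf$compounds, rownames(labels))
  if (length(absent))
    stop("labels missing for compound(s): ", paste(absent, collapse = ", "))
  out <- mld(rf$features, labels[rf$compounds, , drop = FALSE],
             gene_ids = rf$retained_genes,
             sample_ids = rf$compounds)
  attr(out, "retained_genes") <- rf$retained_genes
  out
}

#' Linearly separable multi-label benchmark
#'
#' Fixed construction used as a learning sanity benchmark: standard
#' normal features, one random orthonormal direction per label, labels
#' set by the sign of the projection, and every sample pushed along the
#' label directions until each projection has magnitude at least
#' `margin`.  Because the directions are orthonormal the pushes do not
#' interact, so every label is linearly separable with the stated
#' margin and a linear scorer reaches in-sample subset accuracy 1;
#' per-label prevalence is ~0.5.
#'
#' @param n samples.
#' @param dim feature dimension (must be >= L).
#' @param L number of labels.
#' @param seed integer RNG seed.
#' @param margin minimal projection magnitude.
#' @return an [mld()] dataset; attribute `"directions"` holds the
#'   dim x L orthonormal label directions.
#' @export
make_separable_benchmark <- function(n, dim, L, seed = 1L, margin = 0.5) {
  if (dim < L) stop("dim must be at least L for orthonormal label directions")
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(dim * dim), dim, dim)))[, seq_len(L),
                                                           drop = FALSE]
  X <- matrix(stats::rnorm(n * dim), n, dim)
  S <- X %*% W
  Y <- (S > 0) * 1
  push <- pmax(margin - abs(S), 0) * sign(S)
  X <- X + push %*% t(W)
  out <- mld(X, Y, sample_ids = sprintf("bm%04d", seq_len(n)))
  attr(out, "directions") <- W
  out
}
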