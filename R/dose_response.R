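#' Control parameters for sigmoid dose-response fitting
#'
#' The three dose levels (low, middle, high) are coded on an ordinal
#' log-like axis, 1/2/3 by default, because absolute doses differ per
#' compound.  A fit is declared invalid when its residual sum of squares
#' exceeds `rss_tolerance` (the data cannot form a sigmoid curve), when
#' the response range is below `flat_tolerance` (no dose signal), or when
#' the optimizer returns non-finite parameters.
#'
#' @param dose_codes strictly increasing numeric codes for low/middle/high.
#' @param rss_tolerance maximal residual sum of squares of a valid fit,
#'   in squared expression units.
#' @param flat_tolerance minimal response range (max - min) of a valid
#'   fit, in expression units.
#' @param ec50_margin how far beyond the dose-code range the half-response
#'   point may lie.
#' @param slope_range magnitude bounds of the sigmoid steepness explored
#'   by the grid stage.
#' @return list of class `"dr_control"`.
#' @export
dose_response_control <- function(dose_codes = c(1, 2, 3),
                                  rss_tolerance = 0.1,
                                  flat_tolerance = 0.3,
                                  ec50_margin = 0.75,
                                  slope_range = c(0.4, 16)) {
  if (length(dose_codes) != 3L || any(diff(dose_codes) <= 0))
    stop("dose_codes must be 3 strictly increasing values")
  if (rss_tolerance <= 0 || flat_tolerance <= 0)
    stop("tolerances must be positive")
  structure(list(dose_codes = dose_codes, rss_tolerance = rss_tolerance,
                 flat_tolerance = flat_tolerance, ec50_margin = ec50_margin,
                 slope_range = slope_range),
            class = "dr_control")
}

# candidate (ec50, slope) grid used by the coarse search stage
dr_grid <- function(control) {
  d <- control$dose_codes
  ec50 <- seq(d[1L] - control$ec50_margin, d[3L] + control$ec50_margin,
              length.out = 17L)
  mag <- exp(seq(log(control$slope_range[1L]), log(control$slope_range[2L]),
                 length.out = 9L))
  slope <- c(-rev(mag), mag)
  list(ec50 = rep(ec50, times = length(slope)),
       slope = rep(slope, each = length(ec50)))
}

# For the 3-parameter logistic with the baseline pinned to the first
# response, the amplitude (plateau - baseline) enters linearly, so for any
# (ec50, slope) the optimal amplitude and the residual sum of squares have
# closed forms.  Y: n x 3 responses; returns the best candidate per row.
dr_score_candidates <- function(Y, ec50, slope, dose_codes) {
  yc <- Y - Y[, 1L]                               # centred on pinned baseline
  ycss <- rowSums(yc^2)
  C <- length(ec50)
  S <- matrix(0, C, 3L)
  for (j in 1:3) S[, j] <- stats::plogis(slope * (dose_codes[j] - ec50))
  A <- yc %*% t(S)                                # n x C
  ssum <- rowSums(S^2)
  score <- sweep(A^2, 2L, ssum, "/")              # rss = ycss - score
  best <- max.col(score, ties.method = "first")
  amp <- A[cbind(seq_len(nrow(Y)), best)] / ssum[best]
  list(ec50 = ec50[best], slope = slope[best], amp = amp,
       rss = pmax(ycss - score[cbind(seq_len(nrow(Y)), best)], 0))
}

# vectorized local refinement around per-row centres
dr_zoom <- function(Y, ec50_c, slope_c, dose_codes, de, fs) {
  n <- nrow(Y)
  yc <- Y - Y[, 1L]
  ycss <- rowSums(yc^2)
  off <- expand.grid(de = de, fs = fs)
  K <- nrow(off)
  best_score <- rep(-Inf, n)
  best_e <- ec50_c; best_s <- slope_c; best_a <- rep(0, n)
  for (k in seq_len(K)) {
    e <- ec50_c + off$de[k]
    s <- slope_c * off$fs[k]
    A <- rep(0, n); ssum <- rep(0, n)
    for (j in 1:3) {
      sig <- stats::plogis(s * (dose_codes[j] - e))
      A <- A + sig * yc[, j]
      ssum <- ssum + sig^2
    }
    sc <- ifelse(ssum > 0, A^2 / ssum, 0)
    upd <- sc > best_score
    best_score[upd] <- sc[upd]
    best_e[upd] <- e[upd]; best_s[upd] <- s[upd]
    best_a[upd] <- (A / pmax(ssum, .Machine$double.eps))[upd]
  }
  list(ec50 = best_e, slope = best_s, amp = best_a,
       rss = pmax(ycss - best_score, 0))
}

dr_fit_matrix <- function(Y, control) {
  g <- dr_grid(control)
  fit <- dr_score_candidates(Y, g$ec50, g$slope, control$dose_codes)
  fit <- dr_zoom(Y, fit$ec50, fit$slope, control$dose_codes,
                 de = seq(-0.15, 0.15, length.out = 7L),
                 fs = exp(seq(log(0.7), log(1.45), length.out = 7L)))
  fit <- dr_zoom(Y, fit$ec50, fit$slope, control$dose_codes,
                 de = seq(-0.04, 0.04, length.out = 7L),
                 fs = exp(seq(log(0.92), log(1.09), length.out = 7L)))
  baseline <- Y[, 1L]
  plateau <- baseline + fit$amp
  # maximal response of the fitted curve over the tested dose range: the
  # asymptote itself is not identifiable from three points (a family of
  # logistics interpolates them), but the curve value at the extreme doses is
  d <- control$dose_codes
  f_lo <- baseline + fit$amp * stats::plogis(fit$slope * (d[1L] - fit$ec50))
  f_hi <- baseline + fit$amp * stats::plogis(fit$slope * (d[3L] - fit$ec50))
  rng <- apply(Y, 1L, function(r) diff(range(r)))
  valid <- is.finite(plateau) & is.finite(fit$ec50) & is.finite(fit$slope) &
    fit$rss <= control$rss_tolerance & rng >= control$flat_tolerance
  data.frame(r_max = pmax(baseline, f_lo, f_hi), plateau = plateau,
             ec50 = fit$ec50, slope = fit$slope, baseline = baseline,
             rss = fit$rss, valid = valid)
}

#' Fit a sigmoid dose-response curve to one gene's dose triple
#'
#' Least-squares fit of the 3-parameter logistic
#' \deqn{r(d) = baseline + (plateau - baseline) / (1 + e^{-slope (d - ec50)})}
#' to exactly three (dose code, response) pairs, with the baseline pinned
#' to the first (low-dose) response.  The feature extracted downstream is
#' the maximal response `r_max`, the largest value the fitted curve takes
#' over the tested dose range (three points do not pin down the
#' asymptote, but they do pin down the curve on the range they span).
#' The amplitude is profiled out in closed form and (ec50, slope) are
#' located by a grid search refined with Nelder-Mead.
#'
#' A fit is `valid` only if the residual sum of squares is at most
#' `control$rss_tolerance` and the responses span at least
#' `control$flat_tolerance`; flat or non-monotone triples therefore fail
#' validity and the gene carries no usable dose signal.
#'
#' @param doses three strictly increasing dose codes (default codes come
#'   from `control`; pass `NULL` to use them).
#' @param responses three expression values, ordered low/middle/high.
#' @param control a [dose_response_control()] list.
#' @return object of class `"dose_fit"`: `r_max`, `plateau`, `ec50`,
#'   `slope`, `baseline`, `rss`, `valid`.
#' @examples
#' y <- 1 + 1 / (1 + exp(-6 * (c(1, 2, 3) - 2.4)))
#' fit_gene_curve(c(1, 2, 3), y)
#' @export
fit_gene_curve <- function(doses = NULL, responses,
                           control = dose_response_control()) {
  if (is.null(doses)) doses <- control$dose_codes
  if (length(doses) != 3L || length(responses) != 3L)
    stop("fit_gene_curve expects exactly 3 (dose, response) pairs")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  ctl <- control
  ctl$dose_codes <- as.numeric(doses)
  Y <- matrix(as.numeric(responses), 1L, 3L)
  fit <- dr_fit_matrix(Y, ctl)
  # Nelder-Mead polish on (ec50, slope) with the amplitude profiled out
  yc <- as.numeric(responses) - responses[1L]
  obj <- function(p) {
    sig <- stats::plogis(p[2L] * (doses - p[1L]))
    ssum <- sum(sig^2)
    if (ssum < .Machine$double.eps) return(sum(yc^2))
    sum(yc^2) - sum(sig * yc)^2 / ssum
  }
  opt <- tryCatch(
    stats::optim(c(fit$ec50, fit$slope), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 500L)),
    error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value) && opt$value <= fit$rss) {
    sig <- stats::plogis(opt$par[2L] * (doses - opt$par[1L]))
    amp <- sum(sig * yc) / max(sum(sig^2), .Machine$double.eps)
    fit$ec50 <- opt$par[1L]; fit$slope <- opt$par[2L]
    fit$plateau <- responses[1L] + amp
    fit$r_max <- max(responses[1L], responses[1L] + amp * sig[1L],
                     responses[1L] + amp * sig[3L])
    fit$rss <- max(opt$value, 0)
    rng <- diff(range(responses))
    fit$valid <- is.finite(fit$plateau) && fit$rss <= control$rss_tolerance &&
      rng >= control$flat_tolerance
  }
  structure(as.list(fit), class = "dose_fit")
}

#' @export
print.dose_fit <- function(x, ...) {
  cat(sprintf(
    "Sigmoid dose-response fit: r_max = %.4f (baseline %.4f, plateau %.4f)\n",
    x$r_max, x$baseline, x$plateau))
  cat(sprintf("  ec50 = %.3f, slope = %.3f, rss = %.3g, valid = %s\n",
              x$ec50, x$slope, x$rss, x$valid))
  invisible(x)
}

#' Build R_max features from an expression table
#'
#' Fits a sigmoid dose-response curve per (compound, gene) across the
#' three dose levels and assembles the feature matrix of maximal
#' responses: one row per compound, one column per retained gene.  A gene
#' is retained only if its fit is valid for at least `min_valid_fraction`
#' of the compounds (default: all of them); genes whose expression cannot
#' form a dose-response curve are dropped, exactly as flat or erratic
#' probes carry no toxicity signal.
#'
#' @param records long-format expression data.frame as returned by
#'   [read_expression_table()] or [simulate_dataset()].
#' @param control a [dose_response_control()] list.
#' @param min_valid_fraction fraction of compounds for which a gene's fit
#'   must be valid to retain the gene.
#' @return list with `features` (compounds x retained genes matrix of
#'   r_max values), `retained_genes`, `compounds`, and `fits` (per
#'   compound-gene data.frame of fitted parameters and validity).
#' @export
build_rmax_features <- function(records, control = dose_response_control(),
                                min_valid_fraction = 1) {
  stopifnot(min_valid_fraction > 0, min_valid_fraction <= 1)
  records$dose_level <- factor(records$dose_level, levels = dose_levels())
  compounds <- unique(records$compound_id)
  genes <- unique(records$gene_id)
  ci <- match(records$compound_id, compounds)
  gi <- match(records$gene_id, genes)
  di <- as.integer(records$dose_level)
  if (anyNA(di)) stop("unknown dose level in records")
  nC <- length(compounds); nG <- length(genes)
  Y <- matrix(NA_real_, nC * nG, 3L)
  Y[cbind((gi - 1L) * nC + ci, di)] <- records$value
  miss <- which(!stats::complete.cases(Y))[1L]
  if (!is.na(miss)) {
    g <- (miss - 1L) %/% nC + 1L; cc <- (miss - 1L) %% nC + 1L
    stop("missing dose triple for compound ", compounds[cc], ", gene ",
         genes[g])
  }
  fits <- dr_fit_matrix(Y, control)
  fits$compound_id <- rep(compounds, times = nG)
  fits$gene_id <- rep(genes, each = nC)
  valid_frac <- colMeans(matrix(fits$valid, nC, nG))
  retained <- genes[valid_frac >= min_valid_fraction]
  rmax <- matrix(fits$r_max, nC, nG, dimnames = list(compounds, genes))
  # for a retained gene with a (rare) invalid compound fit under a relaxed
  # fraction, fall back to the observed maximal response
  obs_max <- matrix(apply(Y, 1L, max), nC, nG)
  rmax[!matrix(fits$valid, nC, nG)] <- obs_max[!matrix(fits$valid, nC, nG)]
  list(features = rmax[, retained, drop = FALSE],
       retained_genes = retained, compounds = compounds, fits = fits)
}
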