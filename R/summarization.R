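#' Probe-pair block for one probe set
#'
#' PM and MM intensities for the probe pairs of a single probe set across a
#' set of arrays. At least three probe pairs are required (the signed-rank
#' detection call and the multiplicative model are meaningless below that).
#'
#' @param probe_set_id string identifier.
#' @param pm,mm probes x arrays matrices of non-negative reals, identical
#'   dimensions.
#' @return object of class `probe_pair_block`.
#' @export
probe_pair_block <- function(probe_set_id, pm, mm) {
  if (!all(dim(pm) == dim(mm))) {
    stop("pm and mm must have identical dimensions", call. = FALSE)
  }
  if (nrow(pm) < 3L) {
    stop(sprintf("probe set '%s': need >= 3 probe pairs, got %d",
                 probe_set_id, nrow(pm)), call. = FALSE)
  }
  if (any(pm < 0) || any(mm < 0)) {
    stop("negative probe intensities", call. = FALSE)
  }
  structure(list(probe_set_id = probe_set_id, pm = pm, mm = mm),
            class = "probe_pair_block")
}

#' Fit the multiplicative probe-set model
#'
#' Alternating least squares fit of the PM-MM differences to the rank-1
#' model `y[j, i] = theta[i] * phi[j]` (array effect times probe affinity)
#' under the scale convention `sum(phi^2) = J` (the probe count). Negative
#' PM-MM differences are kept for fitting; the returned expression values
#' are floored at 0. Outliers are identified against a median-based
#' preliminary fit (robust to a corrupted array's leverage on the
#' least-squares factors): cells with |residual| > 3 robust SDs are marked,
#' and an array (or probe) with marks in more than half of its cells is
#' flagged as an outlier for this probe set. Flagged rows/columns are
#' excluded from the final least-squares fit.
#'
#' @param block a [probe_pair_block()] with >= 2 arrays.
#' @param tol relative convergence tolerance of the alternating fit.
#' @param max_rounds iteration cap.
#' @return object of class `probe_set_fit`: `expression` (per-array, >= 0),
#'   `probe_effects` (`sum(phi^2) = J`), `array_outlier`, `probe_outlier`
#'   (logical vectors).
#' @export
fit_probe_set <- function(block, tol = 1e-6, max_rounds = 100L) {
  stopifnot(inherits(block, "probe_pair_block"))
  y <- block$pm - block$mm            # probes x arrays
  J <- nrow(y); I <- ncol(y)
  if (I < 2L) stop("need >= 2 arrays to fit the model", call. = FALSE)
  if (all(y == 0)) {
    return(structure(list(probe_set_id = block$probe_set_id,
                          expression = numeric(I),
                          probe_effects = rep(1, J),
                          array_outlier = logical(I),
                          probe_outlier = logical(J)),
                     class = "probe_set_fit"))
  }
  fit_cells <- function(mask) {
    # mask: logical probes x arrays, TRUE = use cell
    phi <- rep(1, J)
    theta <- rep(0, I)
    for (r in seq_len(max_rounds)) {
      ym <- y * mask
      theta_new <- colSums(ym * phi) / pmax(colSums(mask * phi^2), .Machine$double.eps)
      phi_new <- as.vector((ym %*% theta_new)) / pmax(as.vector(mask %*% theta_new^2), .Machine$double.eps)
      sc <- sqrt(J / max(sum(phi_new^2), .Machine$double.eps))
      phi_new <- phi_new * sc
      theta_new <- theta_new / sc
      delta <- max(abs(theta_new - theta)) / max(max(abs(theta_new)), .Machine$double.eps)
      theta <- theta_new; phi <- phi_new
      if (delta < tol) break
    }
    if (sum(phi) < 0) { phi <- -phi; theta <- -theta }
    list(theta = theta, phi = phi)
  }
  # Outlier identification uses a median-based preliminary fit: a grossly
  # corrupted array has enough leverage on the least-squares factors to
  # mask its own residuals, while the median updates follow the consensus
  # probe pattern of the clean arrays.
  robust_fit <- function() {
    phi <- rep(1, J)
    theta <- rep(1, I)
    for (r in 1:10) {
      ok_p <- abs(phi) > .Machine$double.eps
      theta <- apply(y[ok_p, , drop = FALSE] / phi[ok_p], 2L, stats::median)
      ok_t <- abs(theta) > .Machine$double.eps
      if (!any(ok_t)) break
      phi <- apply(t(y[, ok_t, drop = FALSE]) / theta[ok_t], 2L, stats::median)
      ssq <- sum(phi^2)
      if (ssq <= .Machine$double.eps) break
      phi <- phi * sqrt(J / ssq)
    }
    list(theta = theta, phi = phi)
  }
  rf <- robust_fit()
  resid <- y - outer(rf$phi, rf$theta)
  s <- stats::mad(as.vector(resid))
  if (is.na(s) || s == 0) s <- stats::sd(as.vector(resid))
  marked <- if (is.na(s) || s == 0) matrix(FALSE, J, I) else abs(resid / s) > 3
  array_out <- colMeans(marked) > 0.5
  probe_out <- rowMeans(marked) > 0.5
  mask <- matrix(TRUE, J, I)
  mask[probe_out, ] <- FALSE
  mask[, array_out] <- FALSE
  if (!any(mask)) mask <- matrix(TRUE, J, I)
  f <- fit_cells(mask)
  structure(list(probe_set_id = block$probe_set_id,
                 expression = pmax(f$theta, 0),
                 probe_effects = f$phi,
                 array_outlier = array_out,
                 probe_outlier = probe_out),
            class = "probe_set_fit")
}

#' Detection-call significance levels
#'
#' One-sided signed-rank p-value cutoffs: below `p_present` the call is
#' Present, between `p_present` and `p_marginal` Marginal, else Absent.
#' Defaults follow the MAS5-style convention (0.04 / 0.06).
#'
#' @param p_present,p_marginal significance levels, `0 < p_present <
#'   p_marginal < 1`.
#' @return list of class `call_params`.
#' @export
call_params <- function(p_present = 0.04, p_marginal = 0.06) {
  stopifnot(p_present > 0, p_present < p_marginal, p_marginal < 1)
  structure(list(p_present = p_present, p_marginal = p_marginal),
            class = "call_params")
}

#' Detection call for one probe set on one array
#'
#' One-sided Wilcoxon signed-rank test of PM - MM > 0 across the probe
#' pairs. Zero differences are discarded (standard signed-rank convention);
#' if all differences are zero the test is degenerate and the call is
#' Absent (p treated as 1). The exact null is used when there are no ties
#' among the absolute differences, otherwise the tie-corrected normal
#' approximation.
#'
#' @param pm,mm per-probe intensities, equal length >= 3.
#' @param params a [call_params()] object.
#' @return one of `"P"`, `"M"`, `"A"`.
#' @export
detection_call <- function(pm, mm, params = call_params()) {
  if (length(pm) != length(mm) || length(pm) < 3L) {
    stop("pm and mm must have equal length >= 3", call. = FALSE)
  }
  d <- pm - mm
  d <- d[d != 0]
  if (!length(d)) return("A")
  exact <- length(d) < 50L && !anyDuplicated(abs(d))
  p <- suppressWarnings(
    stats::wilcox.test(d, alternative = "greater", mu = 0,
                       exact = exact, correct = TRUE)$p.value)
  if (is.na(p)) p <- 1
  if (p < params$p_present) "P" else if (p < params$p_marginal) "M" else "A"
}

#' Exclude arrays flagged as outliers in too many probe sets
#'
#' After the model has been fit for all probe sets, each array's outlier
#' fraction is the share of probe sets that flagged it. Arrays whose
#' fraction strictly exceeds the threshold are discarded; a fraction equal
#' to the threshold is kept.
#'
#' @param per_array_outlier_fraction reals in `[0, 1]`, one per array.
#' @param threshold exclusion threshold in (0, 1); default 0.15.
#' @return integer indices of the excluded arrays (possibly empty).
#' @export
flag_outlier_arrays <- function(per_array_outlier_fraction, threshold = 0.15) {
  stopifnot(threshold > 0, threshold < 1,
            all(per_array_outlier_fraction >= 0),
            all(per_array_outlier_fraction <= 1))
  which(per_array_outlier_fraction > threshold)
}

#' Summarize a set of probe-pair blocks
#'
#' Fits every block, assembles the probe-set x array expression matrix and
#' detection-call matrix, and computes per-array outlier fractions for
#' [flag_outlier_arrays()].
#'
#' @param blocks list of [probe_pair_block()]s over the same arrays.
#' @param params a [call_params()] object of call thresholds.
#' @return list with `values` (probe-set x array matrix), `calls`,
#'   `outlier_fraction` (per array).
#' @export
summarize_blocks <- function(blocks, params = call_params()) {
  stopifnot(length(blocks) >= 1)
  I <- ncol(blocks[[1L]]$pm)
  ids <- vapply(blocks, function(b) b$probe_set_id, character(1))
  values <- matrix(0, length(blocks), I)
  calls <- matrix("A", length(blocks), I)
  outlier <- matrix(FALSE, length(blocks), I)
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    fit <- fit_probe_set(b)
    values[k, ] <- fit$expression
    outlier[k, ] <- fit$array_outlier
    for (i in seq_len(I)) {
      calls[k, i] <- detection_call(b$pm[, i], b$mm[, i], params)
    }
  }
  arr <- colnames(blocks[[1L]]$pm)
  if (is.null(arr)) arr <- sprintf("array_%d", seq_len(I))
  dimnames(values) <- list(ids, arr)
  dimnames(calls) <- list(ids, arr)
  list(values = values, calls = calls, outlier_fraction = colMeans(outlier))
}
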