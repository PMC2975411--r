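#' Invariant-set normalization parameters
#'
#' Controls the iterative rank-difference selection of non-differentially
#' expressed probes. At each iteration both arrays are ranked within the
#' current candidate set; probes whose relative rank difference falls below
#' the current fraction are kept and the fraction shrinks geometrically.
#'
#' @param initial_fraction fraction of the relative rank-difference admitted
#'   at the first iteration, in (0, 1].
#' @param shrink_factor multiplicative shrink of the fraction per iteration,
#'   in (0, 1).
#' @param max_iterations iteration cap.
#' @param min_set_size smallest admissible invariant set (>= 10). For
#'   vectors shorter than 4000 probes the effective floor is scaled down
#'   proportionally (never below 10).
#' @return list of class `invariant_set_params`.
#' @export
invariant_set_params <- function(initial_fraction = 0.05, shrink_factor = 0.9,
                                 max_iterations = 30L, min_set_size = 200L) {
  stopifnot(initial_fraction > 0, initial_fraction <= 1,
            shrink_factor > 0, shrink_factor < 1,
            max_iterations >= 1, min_set_size >= 10)
  structure(list(initial_fraction = initial_fraction,
                 shrink_factor = shrink_factor,
                 max_iterations = as.integer(max_iterations),
                 min_set_size = as.integer(min_set_size)),
            class = "invariant_set_params")
}

.effective_min_set <- function(params, n) {
  if (n < 4000L) max(10L, as.integer(round(params$min_set_size * n / 4000)))
  else params$min_set_size
}

#' Pick the baseline array of a normalization group
#'
#' The baseline is the array whose overall intensity (arithmetic mean of its
#' values) is the median of the group's overall intensities; for an even
#' group size, the lower of the two middle arrays is taken.
#'
#' @param group_values list of per-array intensity vectors.
#' @return integer index of the baseline array within the group.
#' @export
select_baseline <- function(group_values) {
  if (!length(group_values)) stop("empty normalization group", call. = FALSE)
  overall <- vapply(group_values, mean, numeric(1))
  ord <- order(overall)
  ord[floor((length(ord) + 1L) / 2L)]
}

#' Find the invariant probe set between a target array and the baseline
#'
#' Probes whose intensity ranks agree between the two arrays are assumed
#' non-differentially expressed. Iteration stops when the kept set
#' stabilizes, when it would shrink below the minimum size (the previous set
#' is returned), or at the iteration cap.
#'
#' @param target,baseline intensity vectors of equal length.
#' @param params an [invariant_set_params()] object.
#' @return integer vector of probe indices (sorted, into the input vectors).
#' @export
find_invariant_set <- function(target, baseline,
                               params = invariant_set_params()) {
  n <- length(target)
  if (length(baseline) != n) {
    stop(sprintf("target (%d) and baseline (%d) lengths differ",
                 n, length(baseline)), call. = FALSE)
  }
  min_set <- .effective_min_set(params, n)
  if (n < min_set) {
    stop(sprintf("need at least %d probes, got %d", min_set, n),
         call. = FALSE)
  }
  idx <- seq_len(n)
  frac <- params$initial_fraction
  for (it in seq_len(params$max_iterations)) {
    m <- length(idx)
    rd <- abs(rank(target[idx], ties.method = "average") -
              rank(baseline[idx], ties.method = "average")) / m
    keep <- rd < frac
    new_idx <- idx[keep]
    if (length(new_idx) < min_set) return(idx)
    if (length(new_idx) == m) return(new_idx)
    idx <- new_idx
    frac <- frac * params$shrink_factor
  }
  idx
}

#' Fit a monotone normalization curve on invariant-set pairs
#'
#' Knots are running medians of the (target, baseline) pairs ordered by
#' target intensity; an isotonic adjustment enforces a non-decreasing map,
#' which is then interpolated piecewise-linearly (linear extrapolation from
#' the end knots outside the knot range, floored at 0 on application).
#'
#' @param target,baseline intensity values of the invariant probes (equal
#'   length, >= window size).
#' @param window running-median window (odd; capped at `n/10` when the pair
#'   count is small).
#' @return object of class `normalization_curve` with a `knots` matrix
#'   (columns `source`, `target`).
#' @export
fit_normalization_curve <- function(target, baseline, window = 101L) {
  n <- length(target)
  if (length(baseline) != n) stop("pair vectors differ in length", call. = FALSE)
  w <- min(as.integer(window), max(3L, n %/% 10L))
  if (w %% 2L == 0L) w <- w - 1L
  w <- max(w, 3L)
  if (n < w) stop(sprintf("need at least %d pairs, got %d", w, n), call. = FALSE)
  ord <- order(target)
  sx <- stats::runmed(target[ord], w, endrule = "median")
  sy <- stats::runmed(baseline[ord], w, endrule = "median")
  # collapse duplicate source coordinates, then force monotone targets
  agg <- tapply(sy, sx, mean)
  kx <- as.numeric(names(agg))
  ky <- as.numeric(agg)
  o <- order(kx)
  kx <- kx[o]; ky <- ky[o]
  if (length(kx) >= 2L) ky <- stats::isoreg(kx, ky)$yf
  if (length(kx) < 2L) {  # degenerate: constant source, identity fallback
    kx <- c(kx, kx + 1)
    ky <- c(ky, ky + 1)
  }
  structure(list(knots = cbind(source = kx, target = ky), window = w),
            class = "normalization_curve")
}

#' Map intensities through a normalization curve
#'
#' Piecewise-linear interpolation between knots; values outside the knot
#' range are extrapolated linearly from the two end knots and the result is
#' clamped at 0.
#'
#' @param x intensity vector.
#' @param curve a `normalization_curve`.
#' @return normalized intensity vector (same length, >= 0).
#' @export
apply_curve <- function(x, curve) {
  kx <- curve$knots[, "source"]
  ky <- curve$knots[, "target"]
  nk <- length(kx)
  y <- stats::approx(kx, ky, xout = x, rule = 2, ties = "ordered")$y
  lo <- x < kx[1L]
  hi <- x > kx[nk]
  if (any(lo)) {
    s <- (ky[2L] - ky[1L]) / (kx[2L] - kx[1L])
    y[lo] <- ky[1L] + s * (x[lo] - kx[1L])
  }
  if (any(hi)) {
    s <- (ky[nk] - ky[nk - 1L]) / (kx[nk] - kx[nk - 1L])
    y[hi] <- ky[nk] + s * (x[hi] - kx[nk])
  }
  pmax(y, 0)
}

#' Normalize a group of arrays against its baseline
#'
#' The baseline array (median overall intensity) is returned unchanged;
#' every other array is normalized through a curve fitted on its own
#' invariant set against the baseline.
#'
#' @param group list of per-array intensity vectors (equal length) or a
#'   probes x arrays matrix.
#' @param params an [invariant_set_params()] object.
#' @return list with `normalized` (same container type as the input),
#'   `baseline_index`, and `invariant_sizes` (per-array invariant-set size;
#'   `NA` for the baseline).
#' @export
normalize_group <- function(group, params = invariant_set_params()) {
  as_matrix <- is.matrix(group)
  vecs <- if (as_matrix) lapply(seq_len(ncol(group)), function(j) group[, j])
          else group
  if (!length(vecs)) stop("empty normalization group", call. = FALSE)
  b <- select_baseline(vecs)
  base <- vecs[[b]]
  sizes <- rep(NA_integer_, length(vecs))
  out <- vecs
  for (k in seq_along(vecs)) {
    if (k == b) next
    inv <- find_invariant_set(vecs[[k]], base, params)
    sizes[k] <- length(inv)
    curve <- fit_normalization_curve(vecs[[k]][inv], base[inv])
    out[[k]] <- apply_curve(vecs[[k]], curve)
  }
  if (as_matrix) {
    m <- do.call(cbind, out)
    dimnames(m) <- dimnames(group)
    out <- m
  }
  list(normalized = out, baseline_index = b, invariant_sizes = sizes)
}
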