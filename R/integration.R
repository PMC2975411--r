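#' Global median transformation of one expression profile
#'
#' Divides every value of a profile (one array's values across all probe
#' sets) by the profile's median, so that transformed profiles share the
#' median 1.00. The standard sample median is used (middle element for odd
#' counts, midpoint mean for even counts); with an odd probe count the
#' transformed median is exactly 1.
#'
#' @param profile numeric vector of non-negative values, median > 0.
#' @return scaled vector, order preserved.
#' @export
median_transform <- function(profile) {
  m <- stats::median(profile)
  if (!is.finite(m) || m <= 0) {
    stop(sprintf("degenerate profile: median %s is not positive (n = %d, %d zeros)",
                 format(m), length(profile), sum(profile == 0)), call. = FALSE)
  }
  profile / m
}

#' Integrate normalized groups into a single compendium
#'
#' Drops excluded (outlier) samples, applies the global median
#' transformation to every retained profile, and column-binds the groups
#' into one compendium. All groups must share the same probe-id list in the
#' same order.
#'
#' @param groups list of normalized probe x sample value matrices (with
#'   dimnames).
#' @param calls list of call matrices parallel to `groups`.
#' @param annotations annotation table covering all retained samples.
#' @param exclusions list (parallel to `groups`) of excluded sample ids or
#'   column indices per group; `NULL` for none.
#' @return a `compendium` ([validate_compendium()]); attribute `provenance`
#'   holds per-group sizes and exclusions.
#' @export
integrate_groups <- function(groups, calls, annotations, exclusions = NULL) {
  stopifnot(length(groups) >= 1, length(calls) == length(groups))
  if (is.null(exclusions)) exclusions <- vector("list", length(groups))
  ref <- rownames(groups[[1L]])
  for (g in seq_along(groups)) {
    ids <- rownames(groups[[g]])
    if (!identical(ids, ref)) {
      div <- which(ids != ref)[1L]
      if (is.na(div)) div <- min(length(ids), length(ref)) + 1L
      stop(sprintf("group %d probe ids diverge from group 1 at position %d ('%s' vs '%s')",
                   g, div, ids[div] %||% "<missing>", ref[div] %||% "<missing>"),
           call. = FALSE)
    }
  }
  keep_v <- vector("list", length(groups))
  keep_c <- vector("list", length(groups))
  prov <- data.frame(group = seq_along(groups),
                     n_samples = vapply(groups, ncol, integer(1)),
                     n_excluded = 0L)
  for (g in seq_along(groups)) {
    v <- groups[[g]]
    cl <- calls[[g]]
    ex <- exclusions[[g]]
    if (!is.null(ex) && length(ex)) {
      j <- if (is.character(ex)) match(ex, colnames(v)) else as.integer(ex)
      if (anyNA(j)) {
        stop(sprintf("group %d: excluded samples not found: %s", g,
                     paste(ex[is.na(j)], collapse = ", ")), call. = FALSE)
      }
      v <- v[, -j, drop = FALSE]
      cl <- cl[, -j, drop = FALSE]
      prov$n_excluded[g] <- length(j)
    }
    for (jj in seq_len(ncol(v))) v[, jj] <- median_transform(v[, jj])
    keep_v[[g]] <- v
    keep_c[[g]] <- cl
  }
  values <- do.call(cbind, keep_v)
  callm <- do.call(cbind, keep_c)
  ann <- annotations[annotations$sample_id %in% colnames(values), , drop = FALSE]
  comp <- validate_compendium(values, callm, ann)
  attr(comp, "provenance") <- prov
  comp
}

#' Median-transform every profile of a compendium in place
#'
#' Convenience for compendia assembled outside [integrate_groups()] (for
#' example simulated ones): applies [median_transform()] to each sample
#' column.
#'
#' @param compendium a `compendium`.
#' @return the compendium with every column at median 1.00.
#' @export
median_transform_compendium <- function(compendium) {
  stopifnot(inherits(compendium, "compendium"))
  for (j in seq_len(ncol(compendium$values))) {
    compendium$values[, j] <- median_transform(compendium$values[, j])
  }
  compendium
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
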