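#' Configuration of the tissue-selectivity analysis
#'
#' Every tunable of the scoring stage. `theta` is the relative-intensity
#' threshold of the significant-expression predicate (1.0 = array median
#' after global median transformation; 0 makes significance purely
#' call-driven). `min_se` / `max_sc` are the candidate-filter bounds on the
#' significant-expression counts in the experiment and control sets;
#' when `NULL` they default to 10% of Ne and 1% of Nc (rounded down, floors
#' 1 and 0) at partition time. `pseudocount` is the smoothing constant of
#' the frequency-contrast score.
#'
#' @param theta relative-intensity threshold, >= 0.
#' @param min_se minimum significant-expression count in the experiment set
#'   (>= 1), or `NULL` for the 10%-of-Ne default.
#' @param max_sc maximum significant-expression count in the control set
#'   (>= 0), or `NULL` for the 1%-of-Nc default.
#' @param w1,w2 weights of the frequency and expression-level scores.
#' @param pseudocount smoothing constant alpha > 0.
#' @param n_permutations permutations per probe set for the p-value (0 =
#'   skip permutation testing).
#' @param seed integer seed for the permutation stream; each probe set uses
#'   a substream derived from the seed and its probe id, so results do not
#'   depend on evaluation order.
#' @return list of class `selectivity_config`.
#' @export
selectivity_config <- function(theta = 1.0, min_se = NULL, max_sc = NULL,
                               w1 = 1, w2 = 1, pseudocount = 0.1,
                               n_permutations = 0L, seed = 1L) {
  stopifnot(theta >= 0, pseudocount > 0, n_permutations >= 0)
  if (!is.null(min_se)) stopifnot(min_se >= 1)
  if (!is.null(max_sc)) stopifnot(max_sc >= 0)
  structure(list(theta = theta, min_se = min_se, max_sc = max_sc,
                 w1 = w1, w2 = w2, pseudocount = pseudocount,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "selectivity_config")
}

.resolve_filter <- function(config, partition) {
  min_se <- config$min_se %||% max(1L, floor(0.10 * partition$ne))
  max_sc <- config$max_sc %||% floor(0.01 * partition$nc)
  list(min_se = as.integer(min_se), max_sc = as.integer(max_sc))
}

#' Significant-expression predicate
#'
#' A measurement is significant when its detection call is Present and its
#' expression value is at least `theta`. Marginal and Absent calls never
#' qualify; with `theta = 0` significance is defined solely by the call.
#'
#' @param value non-negative relative intensity (vectorized).
#' @param call detection call in `{"P","M","A"}` (vectorized).
#' @param theta threshold >= 0.
#' @return logical vector.
#' @export
is_significant <- function(value, call, theta) {
  call == "P" & value >= theta
}

#' Count significant expression in experiment and control sets
#'
#' @param values,calls per-sample vectors aligned to the partition's sample
#'   universe.
#' @param partition a [partition_by_tissue()] result.
#' @param theta threshold >= 0.
#' @return integer vector `c(Se, Sc)`.
#' @export
count_significant <- function(values, calls, partition, theta) {
  sig <- is_significant(values, calls, theta)
  c(Se = sum(sig[partition$experiment_index]),
    Sc = sum(sig[partition$control_index]))
}

#' Candidate filter on the significance counts
#'
#' A probe set is retained for scoring when `Se >= min_se` and
#' `Sc <= max_sc` (both bounds inclusive).
#'
#' @param Se,Sc significance counts.
#' @param config a [selectivity_config()] with explicit `min_se`/`max_sc`.
#' @return logical (vectorized over `Se`/`Sc`).
#' @export
candidate_filter <- function(Se, Sc, config) {
  if (is.null(config$min_se) || is.null(config$max_sc)) {
    stop("candidate_filter needs explicit min_se and max_sc; resolve them against a partition first",
         call. = FALSE)
  }
  Se >= config$min_se & Sc <= config$max_sc
}

#' Mean expression in the experiment and control sets
#'
#' `Ee` is the mean over exactly the experiment arrays with significant
#' expression (there must be at least one). `Ec` is the mean of the `Se`
#' largest control values — the control arrays are sorted by expression for
#' this probe set and the top `Se` are averaged (ties broken toward the
#' lower sample index; if `Se > Nc` all controls are used).
#'
#' @inheritParams count_significant
#' @return numeric vector `c(Ee, Ec)`.
#' @export
expression_means <- function(values, calls, partition, theta) {
  sig <- is_significant(values, calls, theta)
  e_idx <- partition$experiment_index
  sig_e <- e_idx[sig[e_idx]]
  if (!length(sig_e)) {
    stop("Se = 0: mean experiment expression undefined; apply the candidate filter first",
         call. = FALSE)
  }
  se <- length(sig_e)
  ctrl <- values[partition$control_index]
  k <- min(se, length(ctrl))
  top <- order(-ctrl)[seq_len(k)]  # order() is stable: lower index wins ties
  c(Ee = mean(values[sig_e]), Ec = mean(ctrl[top]))
}

#' Frequency-contrast score (Score1)
#'
#' Log10 ratio of the smoothed significant-expression frequencies in the
#' experiment and control sets:
#' `log10(((Se + alpha)/Ne) / ((Sc + alpha)/Nc))`. The pseudocount `alpha`
#' keeps the score finite when either count is zero.
#'
#' @param Se,Sc significance counts.
#' @param Ne,Nc set sizes (>= 1).
#' @param alpha pseudocount > 0.
#' @return numeric (vectorized).
#' @export
score1 <- function(Se, Sc, Ne, Nc, alpha = 0.1) {
  log10(((Se + alpha) / Ne) / ((Sc + alpha) / Nc))
}

#' Expression-level score (Score2)
#'
#' Log10 fold of the mean significant experiment expression over the
#' top-Se control mean: `log10(Ee/Ec)`. Probe sets with `score2 <= 0`
#' (experiment mean not above the control mean) are excluded from the
#' ranking by the caller.
#'
#' @param Ee,Ec positive means from [expression_means()].
#' @return numeric (vectorized).
#' @export
score2 <- function(Ee, Ec) {
  if (any(Ee <= 0) || any(Ec <= 0)) {
    stop("score2 requires positive means", call. = FALSE)
  }
  log10(Ee / Ec)
}

#' Overall priority score
#'
#' Weighted sum `w1 * score1 + w2 * score2`; the ranking key of the
#' analysis.
#'
#' @param s1,s2 component scores.
#' @param w1,w2 weights (default 1, 1).
#' @return numeric (vectorized).
#' @export
priority_score <- function(s1, s2, w1 = 1, w2 = 1) {
  w1 * s1 + w2 * s2
}

#' Genome-wide ranking of tissue-selective probe sets
#'
#' Runs the full scoring stage for one target tissue: partitions the
#' samples, counts significant expression per probe set, applies the
#' candidate filter, computes the expression means, drops probe sets with
#' `score2 <= 0`, and ranks the rest by descending priority score (ties
#' broken by probe id). With `config$n_permutations > 0` a permutation
#' p-value is attached to every ranked probe set.
#'
#' @param compendium a `compendium`.
#' @param tissue target tissue label.
#' @param config a [selectivity_config()].
#' @return `data.frame` with columns `probe_id`, `Se`, `Sc`, `Ee`, `Ec`,
#'   `fold`, `score1`, `score2`, `score`, and — when permutations were
#'   requested — `p_value` (numeric `k/N`) and `p_label` (`"<1/N"` when no
#'   permutation reached the actual score). Attributes `partition` and
#'   `filter` record the run.
#' @export
rank_tissue <- function(compendium, tissue, config = selectivity_config()) {
  stopifnot(inherits(compendium, "compendium"))
  part <- partition_by_tissue(compendium, tissue)
  filt <- .resolve_filter(config, part)
  v <- compendium$values
  sig <- compendium$calls == "P" & v >= config$theta
  Se <- as.integer(rowSums(sig[, part$experiment_index, drop = FALSE]))
  Sc <- as.integer(rowSums(sig[, part$control_index, drop = FALSE]))
  cand <- which(Se >= filt$min_se & Sc <= filt$max_sc & Se >= 1L)
  out <- data.frame(probe_id = character(0), Se = integer(0), Sc = integer(0),
                    Ee = numeric(0), Ec = numeric(0), fold = numeric(0),
                    score1 = numeric(0), score2 = numeric(0),
                    score = numeric(0), stringsAsFactors = FALSE)
  if (length(cand)) {
    Ee <- numeric(length(cand)); Ec <- numeric(length(cand))
    for (k in seq_along(cand)) {
      m <- expression_means(v[cand[k], ], compendium$calls[cand[k], ],
                            part, config$theta)
      Ee[k] <- m[["Ee"]]; Ec[k] <- m[["Ec"]]
    }
    s1 <- score1(Se[cand], Sc[cand], part$ne, part$nc, config$pseudocount)
    s2 <- log10(Ee / Ec)
    keep <- is.finite(s2) & s2 > 0
    if (any(keep)) {
      out <- data.frame(probe_id = compendium$probe_ids[cand[keep]],
                        Se = Se[cand[keep]], Sc = Sc[cand[keep]],
                        Ee = Ee[keep], Ec = Ec[keep],
                        fold = Ee[keep] / Ec[keep],
                        score1 = s1[keep], score2 = s2[keep],
                        score = priority_score(s1[keep], s2[keep],
                                               config$w1, config$w2),
                        stringsAsFactors = FALSE)
      out <- out[order(-out$score, out$probe_id), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  if (config$n_permutations > 0L && nrow(out)) {
    pv <- vapply(seq_len(nrow(out)), function(r) {
      i <- match(out$probe_id[r], compendium$probe_ids)
      res <- permutation_pvalue(v[i, ], compendium$calls[i, ], part,
                                out$score[r], config,
                                probe_id = out$probe_id[r])
      res$p_value
    }, numeric(1))
    out$p_value <- pv
    out$p_label <- ifelse(pv == 0,
                          sprintf("<%s", format(1 / config$n_permutations,
                                                scientific = FALSE)),
                          format(pv, scientific = FALSE))
  }
  attr(out, "partition") <- part
  attr(out, "filter") <- filt
  out
}

#' Permutation p-value of one probe set's priority score
#'
#' The probe set's per-sample (value, call) pairs are permuted jointly and
#' re-divided into experiment and control sets of the original sizes; the
#' priority score is recomputed for each permutation (including the top-Se
#' control mean). Permutations with `Se = 0` or a non-positive fold score
#' `-Inf` and cannot exceed the actual score. The p-value is the plain
#' fraction of permutations whose score is greater than or equal to the
#' actual score; a zero count is reported as the bound `< 1/n_permutations`.
#'
#' The permutation stream is seeded from `config$seed` combined with a hash
#' of `probe_id`, so p-values are reproducible and independent of the order
#' in which probe sets are processed.
#'
#' @inheritParams count_significant
#' @param actual_score priority score computed on the unpermuted data.
#' @param config a [selectivity_config()] with `n_permutations > 0`.
#' @param probe_id identifier used to derive the substream.
#' @return list with `p_value` (`k/N`), `n_exceed` (`k`), `n_permutations`,
#'   and `label` (decimal string, or `"<1/N"` when `k = 0`).
#' @export
permutation_pvalue <- function(values, calls, partition, actual_score,
                               config, probe_id = "") {
  stopifnot(config$n_permutations > 0)
  sig <- is_significant(values, calls, config$theta)
  k <- perm_exceed_count(as.numeric(values), as.logical(sig),
                         partition$ne, config$n_permutations,
                         actual_score, config$pseudocount,
                         config$w1, config$w2,
                         as.character(probe_id), config$seed)
  p <- k / config$n_permutations
  list(p_value = p, n_exceed = k, n_permutations = config$n_permutations,
       label = if (k == 0L) {
         sprintf("<%s", format(1 / config$n_permutations, scientific = FALSE))
       } else format(p, scientific = FALSE))
}

#' Write a selectivity ranking as TSV
#'
#' Scores are written at 4 decimal places; the p-value column carries the
#' decimal fraction or the `<1/N` bound.
#'
#' @param results a [rank_tissue()] data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_selectivity_results <- function(results, path) {
  df <- results
  for (col in c("Ee", "Ec", "fold", "score1", "score2", "score")) {
    df[[col]] <- sprintf("%.4f", df[[col]])
  }
  if (!is.null(df$p_label)) {
    df$p_value <- df$p_label
    df$p_label <- NULL
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
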