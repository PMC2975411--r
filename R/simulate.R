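#' Configuration of the compendium simulator
#'
#' States the world the generator emulates: a multi-study, multi-tissue
#' compendium of relative intensities with per-study scale effects, a
#' lognormal expression background, planted tissue-selective genes of known
#' fold, and a stochastic detection-call process (call probability rises
#' with expression for background genes; planted genes are Present with
#' `p_present_signal` in their target tissue and leak into controls with
#' `p_present_leak`).
#'
#' @param n_tissues number of tissues.
#' @param samples_per_tissue scalar or per-tissue integer vector.
#' @param n_probe_sets number of probe sets (use an odd count if exact
#'   median-1 profiles are required after median transformation).
#' @param n_selective_per_tissue planted selective genes per tissue.
#' @param fold_range `(low, high)`, low > 1: planted fold drawn uniformly.
#' @param p_present_signal Present probability of a planted gene in its
#'   target tissue.
#' @param p_present_leak Present probability of a planted gene elsewhere.
#' @param background_log_sd sdlog of the lognormal background.
#' @param group_scale_range `(low, high)` multiplicative per-study scale.
#' @param studies_per_tissue studies (scale-effect units) per tissue.
#' @param seed integer seed; the generator is a pure function of this
#'   configuration.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_tissues = 5L, samples_per_tissue = 20L,
                              n_probe_sets = 2001L,
                              n_selective_per_tissue = 20L,
                              fold_range = c(10, 50),
                              p_present_signal = 0.9,
                              p_present_leak = 0.005,
                              background_log_sd = 1.0,
                              group_scale_range = c(0.5, 2),
                              studies_per_tissue = 2L,
                              seed = 1L) {
  stopifnot(n_tissues >= 1, all(samples_per_tissue >= 1),
            n_probe_sets >= 1, n_selective_per_tissue >= 0,
            length(fold_range) == 2, fold_range[1] > 1,
            fold_range[2] >= fold_range[1],
            p_present_signal >= 0, p_present_signal <= 1,
            p_present_leak >= 0, p_present_leak <= 1,
            background_log_sd > 0,
            length(group_scale_range) == 2, group_scale_range[1] > 0,
            group_scale_range[2] >= group_scale_range[1],
            studies_per_tissue >= 1,
            n_selective_per_tissue * n_tissues <= n_probe_sets)
  if (length(samples_per_tissue) == 1L) {
    samples_per_tissue <- rep(as.integer(samples_per_tissue), n_tissues)
  }
  stopifnot(length(samples_per_tissue) == n_tissues)
  structure(list(n_tissues = as.integer(n_tissues),
                 samples_per_tissue = as.integer(samples_per_tissue),
                 n_probe_sets = as.integer(n_probe_sets),
                 n_selective_per_tissue = as.integer(n_selective_per_tissue),
                 fold_range = as.numeric(fold_range),
                 p_present_signal = p_present_signal,
                 p_present_leak = p_present_leak,
                 background_log_sd = background_log_sd,
                 group_scale_range = as.numeric(group_scale_range),
                 studies_per_tissue = as.integer(studies_per_tissue),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a multi-study, multi-tissue compendium with planted signal
#'
#' Background values are lognormal(0, `background_log_sd`), rescaled per
#' study by a uniform draw from `group_scale_range`. Planted genes have
#' their values multiplied by a gene-specific fold (uniform in
#' `fold_range`) in their target tissue's samples. Background calls are
#' Present with a logistic probability in the log of the value relative to
#' the sample's median (slope 1.2, so a value at the sample median is
#' Present with probability 0.5, giving realistic 40-60% Present rates);
#' non-Present background cells are Marginal with probability 0.1, else
#' Absent. Planted genes are Present with `p_present_signal` in target
#' samples and `p_present_leak` elsewhere (never Marginal). Each tissue is
#' its own normalization group, split across `studies_per_tissue` studies.
#'
#' @param config a [simulation_config()].
#' @return list with `compendium` (a `compendium`) and `truth`
#'   (`data.frame` probe_id, tissue, fold for the planted genes).
#' @export
simulate_compendium <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  tissue_of <- rep(tissues, config$samples_per_tissue)
  n <- length(tissue_of)
  g <- config$n_probe_sets
  sample_ids <- sprintf("s%04d", seq_len(n))
  probe_ids <- sprintf("ps%05d", seq_len(g))
  study_of <- character(n)
  for (t in tissues) {
    j <- which(tissue_of == t)
    study_of[j] <- sprintf("%s_study%d", t,
                           rep_len(seq_len(config$studies_per_tissue),
                                   length(j)))
  }
  ann <- sample_annotations(sample_ids, tissue_of,
                            group = paste0("grp_", tissue_of),
                            study = study_of)
  values <- matrix(rlnorm(g * n, meanlog = 0,
                          sdlog = config$background_log_sd),
                   nrow = g, dimnames = list(probe_ids, sample_ids))
  # planted genes: first K*T probes, blocked by tissue
  K <- config$n_selective_per_tissue
  truth <- data.frame(probe_id = character(0), tissue = character(0),
                      fold = numeric(0), stringsAsFactors = FALSE)
  planted <- integer(0)
  if (K > 0L) {
    planted <- seq_len(K * config$n_tissues)
    target <- rep(tissues, each = K)
    fold <- runif(length(planted), config$fold_range[1], config$fold_range[2])
    for (k in seq_along(planted)) {
      j <- which(tissue_of == target[k])
      values[planted[k], j] <- values[planted[k], j] * fold[k]
    }
    truth <- data.frame(probe_id = probe_ids[planted], tissue = target,
                        fold = fold, stringsAsFactors = FALSE)
  }
  # per-study multiplicative scale effects
  studies <- unique(study_of)
  scale_of <- stats::setNames(runif(length(studies),
                                    config$group_scale_range[1],
                                    config$group_scale_range[2]), studies)
  values <- sweep(values, 2L, scale_of[study_of], `*`)
  # detection calls
  calls <- matrix("A", g, n, dimnames = list(probe_ids, sample_ids))
  col_med <- apply(values, 2L, stats::median)
  bg <- setdiff(seq_len(g), planted)
  for (j in seq_len(n)) {
    p_present <- plogis(1.2 * (log(values[bg, j]) - log(col_med[j])))
    u <- runif(length(bg))
    pres <- u < p_present
    marg <- !pres & runif(length(bg)) < 0.1
    cj <- rep("A", length(bg))
    cj[pres] <- "P"
    cj[marg] <- "M"
    calls[bg, j] <- cj
  }
  if (K > 0L) {
    for (k in seq_along(planted)) {
      on_target <- tissue_of == target[k]
      pp <- ifelse(on_target, config$p_present_signal, config$p_present_leak)
      calls[planted[k], ] <- ifelse(runif(n) < pp, "P", "A")
    }
  }
  comp <- validate_compendium(values, calls, ann)
  list(compendium = comp, truth = truth)
}

#' Simulate probe-level PM/MM blocks with known array effects
#'
#' Each probe set follows the rank-1 model `PM = MM + theta[i] * phi[j] +`
#' Gaussian noise, with lognormal array effects theta, normalized probe
#' affinities phi, and a uniform MM background. Arrays listed in
#' `outlier_arrays` are corrupted (their PM cells replaced by heavy-tailed
#' values) in a fraction `corrupt_fraction` of the probe sets, which drives
#' their per-probe-set outlier flags above the 15% exclusion threshold.
#'
#' @param arrays number of arrays (>= 2).
#' @param probe_sets number of probe sets.
#' @param pairs_per_set probe pairs per set (>= 3).
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param outlier_arrays integer indices of arrays to corrupt (may be
#'   empty).
#' @param corrupt_fraction fraction of probe sets in which an outlier array
#'   is corrupted (default 0.2).
#' @param seed integer seed.
#' @return list with `blocks` (list of [probe_pair_block()]),
#'   `theta` (probe_sets x arrays matrix of true array effects), and
#'   `corrupted` (probe_sets x arrays logical).
#' @export
simulate_probe_level <- function(arrays, probe_sets, pairs_per_set,
                                 noise_sd = 0, outlier_arrays = integer(0),
                                 corrupt_fraction = 0.2, seed = 1L) {
  stopifnot(arrays >= 2, pairs_per_set >= 3, probe_sets >= 1,
            noise_sd >= 0, corrupt_fraction >= 0, corrupt_fraction <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  blocks <- vector("list", probe_sets)
  theta_true <- matrix(0, probe_sets, arrays)
  corrupted <- matrix(FALSE, probe_sets, arrays)
  array_ids <- sprintf("array_%02d", seq_len(arrays))
  for (s in seq_len(probe_sets)) {
    theta <- rlnorm(arrays, meanlog = log(100), sdlog = 0.3)
    phi <- abs(rnorm(pairs_per_set, 1, 0.3)) + 0.1
    phi <- phi * sqrt(pairs_per_set / sum(phi^2))
    mm <- matrix(runif(pairs_per_set * arrays, 20, 60),
                 pairs_per_set, arrays)
    pm <- mm + outer(phi, theta) +
      matrix(rnorm(pairs_per_set * arrays, 0, noise_sd),
             pairs_per_set, arrays)
    for (a in outlier_arrays) {
      if (runif(1) < corrupt_fraction) {
        pm[, a] <- mm[, a] + abs(rcauchy(pairs_per_set, 0, 500)) + 500
        corrupted[s, a] <- TRUE
      }
    }
    pm <- pmax(pm, 0)
    colnames(pm) <- colnames(mm) <- array_ids
    blocks[[s]] <- probe_pair_block(sprintf("sim_ps%04d", s), pm, mm)
    theta_true[s, ] <- theta
  }
  colnames(theta_true) <- array_ids
  colnames(corrupted) <- array_ids
  list(blocks = blocks, theta = theta_true, corrupted = corrupted)
}

#' Write a simulated compendium (plus truth table) as TSVs
#'
#' @param sim result of [simulate_compendium()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(sim$compendium$values, file.path(dir, "expression.tsv"))
  write_matrix_tsv(sim$compendium$calls, file.path(dir, "calls.tsv"))
  write_annotations(sim$compendium$annotations,
                    file.path(dir, "annotations.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# Save/restore the global RNG state so generators are pure functions of
# their seed without clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
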