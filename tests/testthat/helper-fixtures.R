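# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A small compendium with explicit values/calls and one tissue per group.
make_compendium <- function(values, calls, tissues) {
  n <- ncol(values)
  ids <- sprintf("s%02d", seq_len(n))
  dimnames(values) <- list(sprintf("p%03d", seq_len(nrow(values))), ids)
  dimnames(calls) <- dimnames(values)
  ann <- sample_annotations(ids, tissues, group = paste0("g_", tissues))
  validate_compendium(values, calls, ann)
}

# Independent oracle: exact one-sided signed-rank p-value by enumerating
# all 2^n sign assignments (n small). Ties in |d| are allowed; the V
# statistic uses average ranks like the test under enumeration.
enum_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 14)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.vector(signs %*% r)
  mean(v_null >= v_obs)
}

# Annotation table shaped like the real compendium partition sizes.
big_annotations <- function(counts) {
  tissues <- rep(names(counts), counts)
  sample_annotations(sprintf("s%05d", seq_along(tissues)), tissues,
                     group = tissues)
}
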