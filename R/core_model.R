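#' @useDynLib tselex, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx median quantile rbinom rcauchy rlnorm rnorm runif
#'   isoreg plogis runmed sd wilcox.test
#' @importFrom utils write.table
"_PACKAGE"

CALL_LEVELS <- c("P", "M", "A")

#' Construct a sample annotation table
#'
#' One row per array: sample id, tissue label, normalization group and
#' (optional) study id. Tissue labels are a user-supplied controlled
#' vocabulary; matching elsewhere in the package is exact string equality
#' after whitespace trimming.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param tissue character vector of tissue labels (non-empty).
#' @param group character vector of normalization-group labels (non-empty).
#'   Arrays in the same group are normalized against a common baseline.
#' @param study optional character vector of study identifiers.
#' @return a `data.frame` with columns `sample_id`, `tissue`, `group`,
#'   `study`.
#' @export
sample_annotations <- function(sample_id, tissue, group, study = NA_character_) {
  sample_id <- trimws(as.character(sample_id))
  tissue <- trimws(as.character(tissue))
  group <- trimws(as.character(group))
  study <- as.character(study)
  n <- length(sample_id)
  if (length(tissue) != n || length(group) != n) {
    stop("sample_id, tissue and group must have equal length", call. = FALSE)
  }
  if (length(study) == 1L) study <- rep(study, n)
  if (anyDuplicated(sample_id)) {
    dup <- unique(sample_id[duplicated(sample_id)])
    stop("duplicate sample ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(tissue)) || any(!nzchar(group))) {
    stop("tissue and group labels must be non-empty", call. = FALSE)
  }
  data.frame(sample_id = sample_id, tissue = tissue, group = group,
             study = study, stringsAsFactors = FALSE)
}

.read_tsv_matrix <- function(path, what) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop(sprintf("%s: need a header line and at least one data row", path),
         call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  # header may or may not carry a leading cell for the probe-id column
  body_len <- length(fields[[2L]])
  sample_ids <- if (length(header) == body_len) header[-1L] else header
  ns <- length(sample_ids)
  np <- length(fields) - 1L
  probe_ids <- character(np)
  m <- matrix(NA_character_, nrow = np, ncol = ns)
  for (i in seq_len(np)) {
    row <- fields[[i + 1L]]
    if (length(row) != ns + 1L) {
      stop(sprintf("%s: line %d has %d fields, expected %d (probe id + %d samples)",
                   path, i + 1L, length(row), ns + 1L, ns), call. = FALSE)
    }
    probe_ids[i] <- row[1L]
    m[i, ] <- row[-1L]
  }
  if (anyDuplicated(probe_ids)) {
    dup <- unique(probe_ids[duplicated(probe_ids)])
    stop(sprintf("%s: duplicate probe ids: %s", path,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  dimnames(m) <- list(probe_ids, sample_ids)
  m
}

#' Read a probe-set by sample expression matrix
#'
#' Tab-separated, UTF-8; first row holds sample ids, first column probe-set
#' ids, body cells non-negative reals with '.' decimal point. Probe and
#' sample order are preserved as in the file.
#'
#' @param path path to the TSV file.
#' @return numeric matrix with probe ids as rownames, sample ids as colnames.
#' @export
read_expression_matrix <- function(path) {
  m <- .read_tsv_matrix(path, "expression")
  v <- suppressWarnings(as.numeric(m))
  bad <- which(is.na(v))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop(sprintf("%s: non-numeric value '%s' at probe '%s', sample '%s'",
                 path, m[i, j], rownames(m)[i], colnames(m)[j]), call. = FALSE)
  }
  neg <- which(v < 0)
  if (length(neg)) {
    i <- ((neg[1L] - 1L) %% nrow(m)) + 1L
    j <- ((neg[1L] - 1L) %/% nrow(m)) + 1L
    stop(sprintf("%s: negative value %s at probe '%s', sample '%s'",
                 path, m[i, j], rownames(m)[i], colnames(m)[j]), call. = FALSE)
  }
  matrix(v, nrow = nrow(m), dimnames = dimnames(m))
}

#' Read a detection-call matrix
#'
#' Same layout as [read_expression_matrix()]; cells are detection calls in
#' `{P, M, A}` (Present / Marginal / Absent), case-insensitive.
#'
#' @param path path to the TSV file.
#' @return character matrix over `{"P","M","A"}` with probe/sample dimnames.
#' @export
read_call_matrix <- function(path) {
  m <- .read_tsv_matrix(path, "call")
  up <- toupper(m)
  bad <- which(!(up %in% CALL_LEVELS))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop(sprintf("%s: unknown call symbol '%s' at probe '%s', sample '%s' (expected P, M or A)",
                 path, m[i, j], rownames(m)[i], colnames(m)[j]), call. = FALSE)
  }
  matrix(up, nrow = nrow(m), dimnames = dimnames(m))
}

#' Read a sample annotation table
#'
#' TSV with header `sample_id  tissue  group  study` (study optional).
#'
#' @param path path to the TSV file.
#' @return annotation `data.frame` as produced by [sample_annotations()].
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "tissue", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing annotation columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (is.null(df$study)) df$study <- NA_character_
  sample_annotations(df$sample_id, df$tissue, df$group, df$study)
}

#' Write an expression or call matrix as TSV
#'
#' Inverse of the readers: first column probe id, header row of sample ids.
#' Numeric values are written at 17 significant digits so that a write/read
#' round trip reproduces the matrix bit-identically.
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path) {
  body <- if (is.numeric(m)) {
    matrix(sprintf("%.17g", m), nrow = nrow(m), dimnames = dimnames(m))
  } else m
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(m)), collapse = "\t"), con)
  writeLines(paste(rownames(m),
                   apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"),
             con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param ann annotation data frame.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble and validate a compendium
#'
#' Checks that the value and call matrices agree in shape and dimnames, that
#' values are non-negative, and that every sample column has exactly one
#' annotation row; samples are reordered so that matrix columns and
#' annotation rows agree. A transcript with an Absent call may still carry a
#' positive expression value — the two matrices are independent channels.
#'
#' @param values numeric probe x sample matrix, non-negative.
#' @param calls character probe x sample matrix over `{"P","M","A"}`.
#' @param annotations annotation table ([sample_annotations()]).
#' @return an object of class `compendium`: list with `values`, `calls`,
#'   `annotations`, `probe_ids`, `sample_ids`.
#' @export
validate_compendium <- function(values, calls, annotations) {
  if (!all(dim(values) == dim(calls))) {
    stop(sprintf("values (%d x %d) and calls (%d x %d) differ in shape",
                 nrow(values), ncol(values), nrow(calls), ncol(calls)),
         call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values matrix must carry probe rownames and sample colnames",
         call. = FALSE)
  }
  if (!identical(rownames(values), rownames(calls))) {
    stop("values and calls disagree in probe ids or order", call. = FALSE)
  }
  if (any(values < 0)) stop("negative expression values", call. = FALSE)
  if (!all(calls %in% CALL_LEVELS)) {
    stop("calls contain symbols outside {P, M, A}", call. = FALSE)
  }
  if (!identical(sort(colnames(values)), sort(colnames(calls)))) {
    stop("values and calls disagree in sample ids", call. = FALSE)
  }
  calls <- calls[, colnames(values), drop = FALSE]
  extra_m <- setdiff(colnames(values), annotations$sample_id)
  extra_a <- setdiff(annotations$sample_id, colnames(values))
  if (length(extra_m) || length(extra_a)) {
    stop(sprintf("sample membership mismatch: in matrix only [%s]; in annotations only [%s]",
                 paste(extra_m, collapse = ", "),
                 paste(extra_a, collapse = ", ")), call. = FALSE)
  }
  annotations <- annotations[match(colnames(values), annotations$sample_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(values = values, calls = calls, annotations = annotations,
                 probe_ids = rownames(values), sample_ids = colnames(values)),
            class = "compendium")
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf("compendium: %d probe sets x %d samples, %d tissues, %d groups\n",
              length(x$probe_ids), length(x$sample_ids),
              length(unique(x$annotations$tissue)),
              length(unique(x$annotations$group))))
  invisible(x)
}

#' Split samples into experiment and control sets for one tissue
#'
#' The experiment set holds every sample annotated with the target tissue;
#' the control set holds all other samples. Both sets must be non-empty.
#'
#' @param compendium a `compendium` (or its annotation table).
#' @param tissue target tissue label (matched exactly after trimming).
#' @return object of class `tissue_partition`: list with `tissue`,
#'   `experiment_index`, `control_index`, `ne`, `nc`.
#' @export
partition_by_tissue <- function(compendium, tissue) {
  ann <- if (inherits(compendium, "compendium")) compendium$annotations
         else compendium
  tissue <- trimws(tissue)
  is_exp <- ann$tissue == tissue
  ne <- sum(is_exp)
  nc <- sum(!is_exp)
  if (ne == 0L) {
    stop(sprintf("no samples annotated with tissue '%s'", tissue),
         call. = FALSE)
  }
  if (nc == 0L) {
    stop(sprintf("tissue '%s' covers every sample; control set is empty",
                 tissue), call. = FALSE)
  }
  structure(list(tissue = tissue,
                 experiment_index = which(is_exp),
                 control_index = which(!is_exp),
                 ne = ne, nc = nc),
            class = "tissue_partition")
}

#' @export
print.tissue_partition <- function(x, ...) {
  cat(sprintf("tissue '%s': Ne = %d experiment, Nc = %d control samples\n",
              x$tissue, x$ne, x$nc))
  invisible(x)
}
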