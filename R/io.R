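#' Read a probe-by-sample expression matrix from delimited text
#'
#' Expects a header row of sample identifiers and a first column of probe
#' identifiers. Values must be numeric log2-scale expression (log-ratios for
#' two-colour designs); any row containing a non-numeric or missing cell is
#' rejected with its row index — post-normalisation matrices are expected to
#' be complete and no imputation is performed. Probe identifiers may repeat
#' (replicate probes prior to [average_replicate_probes()]); sample
#' identifiers must be unique. Identifiers are compared case-sensitively
#' after stripping surrounding whitespace.
#'
#' @param path file path.
#' @param sep `"tab"` (default) or `"comma"`.
#' @return numeric matrix, probes in rows (rownames), samples in columns
#'   (colnames).
#' @export
read_expression_matrix <- function(path, sep = c("tab", "comma")) {
  sep <- match.arg(sep)
  sc <- if (sep == "tab") "\t" else ","
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty expression matrix file: ", path)
  raw <- utils::read.table(path, sep = sc, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("expression matrix needs a probe column and at least one sample column")
  if (nrow(raw) < 1L) stop("expression matrix has no data rows: ", path)
  samples <- trimws(colnames(raw)[-1L])
  dup <- unique(samples[duplicated(samples)])
  if (length(dup))
    stop("duplicated sample identifier(s): ", paste(dup, collapse = ", "))
  probes <- trimws(raw[[1L]])
  vals <- suppressWarnings(
    vapply(raw[-1L], function(col) as.numeric(trimws(col)), numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw))
  bad <- which(apply(vals, 1L, function(r) any(is.na(r))))
  if (length(bad))
    stop("non-numeric or missing value(s) in data row(s): ",
         paste(bad, collapse = ", "))
  dimnames(vals) <- list(probes, samples)
  vals
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression_matrix()]; values round-trip to within 1e-12.
#'
#' @param mat numeric matrix with probe rownames and sample colnames.
#' @param path output file path.
#' @inheritParams read_expression_matrix
#' @export
write_expression_matrix <- function(mat, path, sep = c("tab", "comma")) {
  sep <- match.arg(sep)
  sc <- if (sep == "tab") "\t" else ","
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(probe_id = rownames(mat),
                   matrix(sprintf("%.15g", mat), nrow = nrow(mat),
                          dimnames = list(NULL, colnames(mat))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sc, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a line are collapsed (first occurrence kept);
#' duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return named list; each element is `list(description =, genes =)`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  out <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields) | seq_along(fields) <= 2L]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    nms[i] <- fields[1L]
    out[[i]] <- list(description = fields[2L],
                     genes = unique(fields[-(1:2)]))
  }
  dup <- unique(nms[duplicated(nms)])
  if (length(dup))
    stop("duplicated gene-set name(s): ", paste(dup, collapse = ", "))
  names(out) <- nms
  out
}

#' Write a gene-set collection in GMT format
#' @param collection named list as returned by [read_gmt()].
#' @param path output file path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  lines <- vapply(names(collection), function(nm) {
    el <- collection[[nm]]
    paste(c(nm, el$description, el$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two-column delimited text (probe, gene) with a header row; repeated probe
#' rows accumulate into multi-gene mappings. Probes absent from the map are
#' simply unmapped, never an error.
#'
#' @param path file path.
#' @return named list: probe id -> character vector of gene symbols.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("probe map needs two columns (probe, gene)")
  probe <- trimws(df[[1L]]); gene <- trimws(df[[2L]])
  keep <- nzchar(gene)
  lapply(split(gene[keep], factor(probe[keep], levels = unique(probe[keep]))),
         unique)
}

#' Write a probe-to-gene mapping table
#' @param map named list, probe id -> character vector of genes.
#' @param path output file path.
#' @export
write_probe_map <- function(map, path) {
  probe <- rep(names(map), lengths(map))
  df <- data.frame(probe = probe, gene = unlist(map, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' CSV with named header columns `id`, `sex`, `age`, `bmi`, `glucose`
#' (fasting, mmol/l), `insulin` (fasting, mU/l) and optionally `homa_ir`.
#' Glucose, insulin and BMI must be strictly positive.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("id", "sex", "age", "bmi", "glucose", "insulin")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  df$id <- trimws(as.character(df$id))
  for (v in c("age", "bmi", "glucose", "insulin"))
    df[[v]] <- as.numeric(df[[v]])
  if (any(!is.finite(df$glucose)) || any(df$glucose <= 0))
    stop("fasting glucose must be strictly positive")
  if (any(!is.finite(df$insulin)) || any(df$insulin <= 0))
    stop("fasting insulin must be strictly positive")
  if (any(!is.finite(df$bmi)) || any(df$bmi <= 0))
    stop("BMI must be strictly positive")
  df
}

#' Average replicate probes
#'
#' Collapses rows sharing a probe identifier to their arithmetic mean per
#' sample (the usual replicate-probe averaging step on post-normalisation
#' two-colour arrays). Output rows keep the order of first occurrence;
#' idempotent.
#'
#' @param mat numeric matrix with (possibly repeated) probe rownames.
#' @return matrix with one row per unique probe id.
#' @export
average_replicate_probes <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  ids <- factor(rownames(mat), levels = unique(rownames(mat)))
  sums <- rowsum(mat, group = ids, reorder = FALSE)
  counts <- tabulate(ids, nbins = nlevels(ids))
  out <- sums / counts
  rownames(out) <- levels(ids)
  out
}

#' Construct two-class cohort labels
#'
#' @param sample_ids character vector of sample identifiers.
#' @param classes character/factor of class memberships, parallel to
#'   `sample_ids`.
#' @param class_order optional explicit class order; the first class is the
#'   reference for log2 fold-change orientation and for tie-breaking.
#' @return named factor with exactly two levels.
#' @export
cohort_labels <- function(sample_ids, classes, class_order = NULL) {
  sample_ids <- trimws(as.character(sample_ids))
  classes <- as.character(classes)
  stopifnot(length(sample_ids) == length(classes), !anyDuplicated(sample_ids))
  lev <- if (is.null(class_order)) unique(classes) else class_order
  if (length(lev) != 2L)
    stop("exactly two classes are required, got: ", paste(lev, collapse = ", "))
  f <- factor(classes, levels = lev)
  if (anyNA(f)) stop("class label outside declared class order")
  if (any(table(f) < 2L)) stop("each class needs at least 2 samples")
  names(f) <- sample_ids
  f
}

# Internal: check labels against a matrix and return them aligned to columns.
.align_labels <- function(mat, labels) {
  if (is.null(names(labels))) stop("labels must be named by sample id")
  missing <- setdiff(names(labels), colnames(mat))
  if (length(missing))
    stop("labelled sample(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  labels[colnames(mat)[colnames(mat) %in% names(labels)]]
}
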