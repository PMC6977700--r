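#' Construct an expression matrix for one transcript class
#'
#' A thin container for a genes x samples matrix of log2-scale expression
#' values. Input data are assumed to be already log2-transformed and
#' normalized (as in processed GEO series matrices); no normalization is
#' performed here. Gene identifiers are opaque strings; a gene's transcript
#' class is defined by the matrix it lives in, not by any annotation lookup.
#'
#' @param values Numeric matrix with gene ids as rownames and sample ids as
#'   colnames. All values must be finite; ids must be unique.
#' @param transcript_class One of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` and `transcript_class`.
#' @export
expression_matrix <- function(values, transcript_class = c("mRNA", "lncRNA", "miRNA")) {
  transcript_class <- match.arg(transcript_class)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicated gene ids in expression matrix")
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids in expression matrix")
  if (!all(is.finite(values))) stop("expression matrix contains non-finite values")
  structure(list(values = values, transcript_class = transcript_class),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %s: %d genes x %d samples\n",
              x$transcript_class, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x An `expression_matrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix to a set of samples
#' @param x An `expression_matrix`.
#' @param samples Sample ids to keep (order preserved as given).
#' @return An `expression_matrix` restricted to `samples`.
#' @export
subset_samples <- function(x, samples) {
  missing <- setdiff(samples, sample_ids(x))
  if (length(missing)) {
    stop("samples absent from ", x$transcript_class, " matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  expression_matrix(x$values[, samples, drop = FALSE], x$transcript_class)
}

#' Collapse duplicated gene rows to their elementwise median
#'
#' When several measurement rows (e.g. probes) map to the same gene, the
#' per-sample median across those rows is taken as the gene's expression
#' value. Row order within a gene does not affect the result.
#'
#' @param values Numeric matrix, one row per measurement.
#' @param gene_ids Character vector of gene ids, one per row of `values`.
#' @return Numeric matrix with one row per unique gene id (first-appearance
#'   order), colnames preserved.
#' @export
collapse_duplicates <- function(values, gene_ids) {
  if (!is.matrix(values)) values <- matrix(values, nrow = length(gene_ids))
  if (nrow(values) != length(gene_ids)) {
    stop("length of 'gene_ids' must equal nrow(values)")
  }
  uniq <- unique(gene_ids)
  if (length(uniq) == length(gene_ids)) {
    rownames(values) <- gene_ids
    return(values)
  }
  idx <- split(seq_along(gene_ids), factor(gene_ids, levels = uniq))
  med <- vapply(idx, function(i) {
    apply(values[i, , drop = FALSE], 2L, stats::median)
  }, FUN.VALUE = numeric(ncol(values)))
  out <- if (ncol(values) == 1L) matrix(med, ncol = 1L) else t(med)
  rownames(out) <- uniq
  colnames(out) <- colnames(values)
  out
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row, gene ids in the first column and one column per
#' sample. The delimiter is auto-detected among tab and comma (ties toward
#' tab). Rows sharing a gene id are collapsed to their median via
#' [collapse_duplicates()].
#'
#' @param path Path to a TSV/CSV file.
#' @param transcript_class One of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @param delim Optional delimiter override.
#' @param verbose Print the loaded dimensions.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, transcript_class, delim = NULL, verbose = TRUE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  delim <- delim %||% detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty expression matrix in ", path)
  ids <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) stop("duplicated sample ids in ", path)
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s' in %s",
                 ids[bad[1L, 1L]], samples[bad[1L, 2L]], path))
  }
  colnames(num) <- samples
  collapsed <- collapse_duplicates(num, ids)
  out <- expression_matrix(collapsed, transcript_class)
  if (verbose) {
    message(sprintf("Loaded %d %s genes x %d samples from %s (%d input rows)",
                    nrow(collapsed), out$transcript_class, ncol(collapsed),
                    basename(path), length(ids)))
  }
  out
}

#' Write an expression matrix to tab-delimited text
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces them bit-identically.
#'
#' @param x An `expression_matrix`.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  vals <- x$values
  txt <- matrix(sprintf("%.17g", vals), nrow = nrow(vals))
  df <- data.frame(gene_id = rownames(vals), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(vals))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `group` and optionally `outcome`.
#'
#' @param path Path to a TSV/CSV file.
#' @param delim Optional delimiter override.
#' @return A data frame with columns `sample_id`, `group`, `outcome`.
#' @export
read_metadata <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  delim <- delim %||% detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(df))) {
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  if (!"outcome" %in% colnames(df)) df$outcome <- NA_character_
  df[, c("sample_id", "group", "outcome")]
}

#' Restrict matched expression matrices to their common samples
#'
#' Samples missing from any of the matrices (or from the metadata, when
#' given) are dropped, with a message listing how many were removed from
#' each input. At least 4 common samples are required, since downstream
#' correlation p-values need n > 3.
#'
#' @param expr Named list of `expression_matrix` objects.
#' @param metadata Optional metadata data frame (see [read_metadata()]).
#' @return List with elements `expr` (trimmed list) and `metadata`.
#' @export
intersect_samples <- function(expr, metadata = NULL) {
  stopifnot(length(expr) >= 1L)
  common <- Reduce(intersect, lapply(expr, sample_ids))
  if (!is.null(metadata)) common <- intersect(common, metadata$sample_id)
  if (length(common) < 4L) {
    stop("fewer than 4 samples shared across inputs (correlation needs n > 3)")
  }
  for (nm in names(expr)) {
    dropped <- setdiff(sample_ids(expr[[nm]]), common)
    if (length(dropped)) {
      message(sprintf("Dropping %d sample(s) from %s matrix not shared by all inputs",
                      length(dropped), nm))
    }
    expr[[nm]] <- subset_samples(expr[[nm]], common)
  }
  if (!is.null(metadata)) {
    metadata <- metadata[match(common, metadata$sample_id), , drop = FALSE]
    rownames(metadata) <- NULL
  }
  list(expr = expr, metadata = metadata)
}

#' Construct a miRNA-target interaction set
#'
#' @param mirna_to_mrna Named list: miRNA id -> character vector of mRNA ids.
#' @param mirna_to_lncrna Named list: miRNA id -> character vector of lncRNA ids.
#' @return An object of class `interaction_set`.
#' @export
interaction_set <- function(mirna_to_mrna, mirna_to_lncrna) {
  clean <- function(m, what) {
    if (length(m) == 0L) stop("empty ", what, " interaction map")
    if (is.null(names(m)) || any(names(m) == "")) stop(what, " map must be named by miRNA")
    lapply(m, function(v) sort(unique(as.character(v))))
  }
  structure(list(mirna_to_mrna = clean(mirna_to_mrna, "miRNA-mRNA"),
                 mirna_to_lncrna = clean(mirna_to_lncrna, "miRNA-lncRNA")),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf("<interaction_set> %d miRNA-mRNA pairs (%d miRNAs), %d miRNA-lncRNA pairs (%d miRNAs)\n",
              sum(lengths(x$mirna_to_mrna)), length(x$mirna_to_mrna),
              sum(lengths(x$mirna_to_lncrna)), length(x$mirna_to_lncrna)))
  invisible(x)
}

.read_pair_file <- function(path, what, delim = NULL) {
  if (!file.exists(path)) stop(what, " interaction file not found: ", path)
  delim <- delim %||% detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty ", what, " interaction file: ", path)
  df <- unique(df[, 1:2])
  split(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read miRNA-target interaction tables
#'
#' Each file is two-column delimited text (miRNA, target) with a header row;
#' duplicated pairs are removed.
#'
#' @param path_mrna Path to the miRNA-mRNA pair table.
#' @param path_lncrna Path to the miRNA-lncRNA pair table.
#' @param delim Optional delimiter override.
#' @param verbose Print pair counts.
#' @return An [interaction_set()].
#' @export
read_interactions <- function(path_mrna, path_lncrna, delim = NULL, verbose = TRUE) {
  m2m <- .read_pair_file(path_mrna, "miRNA-mRNA", delim)
  m2l <- .read_pair_file(path_lncrna, "miRNA-lncRNA", delim)
  out <- interaction_set(m2m, m2l)
  if (verbose) {
    message(sprintf("Loaded %d miRNA-mRNA and %d miRNA-lncRNA unique interactions",
                    sum(lengths(out$mirna_to_mrna)), sum(lengths(out$mirna_to_lncrna))))
  }
  out
}

#' Restrict an interaction set to profiled genes
#'
#' @param interactions An `interaction_set`.
#' @param mrna_ids,lncrna_ids Target ids to keep.
#' @param mirna_ids Optional miRNA ids to keep (e.g. the profiled miRNAs).
#' @return A trimmed `interaction_set`.
#' @export
restrict_interactions <- function(interactions, mrna_ids, lncrna_ids, mirna_ids = NULL) {
  trim <- function(m, keep_targets) {
    m <- lapply(m, function(v) v[v %in% keep_targets])
    m <- m[lengths(m) > 0L]
    if (!is.null(mirna_ids)) m <- m[names(m) %in% mirna_ids]
    m
  }
  m2m <- trim(interactions$mirna_to_mrna, mrna_ids)
  m2l <- trim(interactions$mirna_to_lncrna, lncrna_ids)
  if (length(m2m) == 0L || length(m2l) == 0L) {
    stop("no interactions remain after restricting to profiled genes")
  }
  interaction_set(m2m, m2l)
}

# Flatten an interaction map to a two-column data frame
.pairs_df <- function(m, target_col) {
  out <- data.frame(mirna = rep(names(m), lengths(m)),
                    target = unlist(m, use.names = FALSE),
                    stringsAsFactors = FALSE)
  names(out)[2L] <- target_col
  out
}
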