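#' Per-stage group means of an expression matrix
#'
#' @param expr An [expression_matrix()].
#' @param metadata Metadata data frame (see [read_metadata()]).
#' @param stages Ordered character vector of group labels to use as stages;
#'   defaults to the order of first appearance in `metadata$group`.
#' @return Numeric matrix, genes x stages.
#' @export
stage_means <- function(expr, metadata, stages = NULL) {
  stages <- stages %||% unique(metadata$group)
  missing <- setdiff(stages, metadata$group)
  if (length(missing)) stop("stage label(s) absent from metadata: ",
                            paste(missing, collapse = ", "))
  out <- vapply(stages, function(s) {
    ids <- intersect(metadata$sample_id[metadata$group == s], sample_ids(expr))
    if (length(ids) == 0L) stop("no samples for stage '", s, "' in expression matrix")
    rowMeans(expr$values[, ids, drop = FALSE])
  }, FUN.VALUE = numeric(nrow(expr$values)))
  colnames(out) <- stages
  out
}

#' Standardize stage profiles gene-wise
#'
#' Rescales each row (a gene's stage-mean profile) to mean 0, sd 1 so that
#' clustering groups genes by trend shape rather than expression level.
#'
#' @param profiles Numeric matrix, genes x stages (>= 2 stages).
#' @return Matrix of the same shape.
#' @export
standardize_profiles <- function(profiles) {
  if (ncol(profiles) < 2L) stop("need at least 2 stages")
  sdv <- apply(profiles, 1L, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat)) {
    stop("constant stage profile for gene(s): ",
         paste(utils::head(rownames(profiles)[flat], 5L), collapse = ", "))
  }
  (profiles - rowMeans(profiles)) / sdv
}

#' Fuzzy c-means clustering of expression trend profiles
#'
#' Standard fuzzy c-means: memberships are initialized at random (seeded),
#' then centroids (membership^m weighted means) and memberships (inverse
#' distance ratios with exponent 2/(m-1)) are updated alternately until the
#' largest membership change falls below `tol` or `max_iter` is reached.
#' The objective `sum(u^m * d^2)` is recorded per iteration and is
#' non-increasing by construction of the alternating updates.
#'
#' @param profiles Standardized genes x stages matrix.
#' @param k Number of clusters (>= 2, < number of genes).
#' @param m Fuzzifier (> 1, default 2).
#' @param seed Integer seed for the initialization.
#' @param max_iter,tol Convergence controls.
#' @return List of class `cluster_result`: `gene_ids`, `membership`
#'   (genes x k, rows sum to 1), `hard_labels` (argmax cluster),
#'   `centroids` (k x stages), `objective` (per-iteration trace),
#'   `iterations`.
#' @export
fuzzy_cmeans <- function(profiles, k, m = 2, seed = 1L, max_iter = 500L, tol = 1e-6) {
  if (k < 2L) stop("'k' must be at least 2")
  if (m <= 1) stop("fuzzifier 'm' must exceed 1")
  n <- nrow(profiles)
  if (n <= k) stop("need more genes than clusters")
  set.seed(seed)
  U <- matrix(stats::runif(n * k), n, k)
  U <- U / rowSums(U)
  expo <- 1 / (m - 1)
  obj <- numeric(0L)
  row_sq <- rowSums(profiles^2)
  for (it in seq_len(max_iter)) {
    Um <- U^m
    C <- (t(Um) %*% profiles) / colSums(Um)
    D2 <- outer(row_sq, rowSums(C^2), "+") - 2 * profiles %*% t(C)
    D2 <- pmax(D2, 0)
    zero <- D2 < 1e-14
    Unew <- 1 / (D2^expo * rowSums((1 / pmax(D2, 1e-300))^expo))
    hit <- rowSums(zero) > 0L
    if (any(hit)) Unew[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    obj <- c(obj, sum(Unew^m * D2))
    delta <- max(abs(Unew - U))
    U <- Unew
    if (delta < tol) break
  }
  dimnames(U) <- list(rownames(profiles), paste0("cluster_", seq_len(k)))
  dimnames(C) <- list(paste0("cluster_", seq_len(k)), colnames(profiles))
  hard <- max.col(U, ties.method = "first")
  names(hard) <- rownames(profiles)
  structure(list(gene_ids = rownames(profiles), membership = U,
                 hard_labels = hard, centroids = C,
                 objective = obj, iterations = it),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d genes, %d clusters, %d iterations\n",
              length(x$gene_ids), ncol(x$membership), x$iterations))
  print(table(cluster = x$hard_labels))
  invisible(x)
}

#' Co-expressed mRNA partners of a non-coding RNA
#'
#' Returns the mRNAs whose Pearson correlation with the given profile
#' satisfies `|r| > r_cut` and `p < p_cut` over the shared samples.
#'
#' @param ncrna_profile Named numeric vector (names = sample ids).
#' @param mrna_expr mRNA [expression_matrix()].
#' @param r_cut Absolute correlation threshold (default 0.7).
#' @param p_cut P-value threshold (default 0.01).
#' @return Sorted character vector of mRNA ids.
#' @export
coexpressed_partners <- function(ncrna_profile, mrna_expr, r_cut = 0.7, p_cut = 0.01) {
  shared <- intersect(names(ncrna_profile), sample_ids(mrna_expr))
  if (length(shared) < 4L) stop("fewer than 4 shared samples")
  x <- ncrna_profile[shared]
  if (stats::sd(x) == 0) stop("constant ncRNA profile")
  z <- .standardize_rows(mrna_expr$values[, shared, drop = FALSE])
  zx <- (x - mean(x)) / stats::sd(x)
  r <- as.vector(z %*% zx) / (length(shared) - 1L)
  p <- .cor_pval(r, length(shared))
  keep <- !is.na(r) & abs(r) > r_cut & p < p_cut
  sort(rownames(z)[keep])
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member genes, tab-separated. The
#' description field is used as the parent pathway label (falling back to
#' the set name when empty), enabling best-subset retention in
#' [geneset_enrichment()].
#'
#' @param path Path to a GMT file.
#' @return List of class `gene_set_collection` with `sets` (named list of
#'   character vectors) and `parent` (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): fewer than 3 fields")
  nm <- vapply(parts, `[[`, character(1L), 1L)
  desc <- vapply(parts, `[[`, character(1L), 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  parent <- ifelse(nzchar(desc), desc, nm)
  names(parent) <- nm
  structure(list(sets = sets, parent = parent), class = "gene_set_collection")
}

#' Hypergeometric gene-set enrichment with best-subset retention
#'
#' For each set, tests over-representation of the query among the universe
#' with the hypergeometric upper tail P(X >= k). When several sets share a
#' parent pathway label (e.g. sub-pathways of one pathway), only the
#' lowest-p set per parent is retained.
#'
#' @param query Character vector of gene ids (must lie in `universe`).
#' @param collection A [read_gmt()] result, or a named list of character
#'   vectors (each set is then its own parent).
#' @param universe Character vector of background gene ids.
#' @param alpha Significance threshold (default 0.05).
#' @param retain_best_per_parent Apply the per-parent retention rule
#'   (default TRUE).
#' @return Data frame with columns `set`, `parent`, `k` (query hits), `K`
#'   (set size in universe), `n_query`, `N_universe`, `p`, `significant`,
#'   ordered by p.
#' @export
geneset_enrichment <- function(query, collection, universe, alpha = 0.05,
                               retain_best_per_parent = TRUE) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(query) == 0L) stop("empty query gene set")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  }
  if (!inherits(collection, "gene_set_collection")) {
    collection <- structure(list(sets = collection,
                                 parent = stats::setNames(names(collection), names(collection))),
                            class = "gene_set_collection")
  }
  sets <- lapply(collection$sets, intersect, y = universe)
  keep <- lengths(sets) > 0L
  sets <- sets[keep]
  if (length(sets) == 0L) stop("no gene set overlaps the universe")
  N <- length(universe)
  n <- length(query)
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, query)), integer(1L))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set = names(sets), parent = unname(collection$parent[names(sets)]),
                    k = unname(k), K = unname(K), n_query = n, N_universe = N,
                    p = unname(p), stringsAsFactors = FALSE)
  if (retain_best_per_parent) {
    out <- out[order(out$p, out$set), , drop = FALSE]
    out <- out[!duplicated(out$parent), , drop = FALSE]
  }
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
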