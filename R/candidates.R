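#' Configuration for candidate triplet discovery
#'
#' @param hyper_alpha Significance level for the shared-miRNA hypergeometric
#'   test (default 0.05).
#' @param corr_alpha Significance level for the three link correlations
#'   (default 0.05).
#' @param percentile_cut Percentile (0-100, default 90) of the class-wise
#'   distribution of |r| that a link must reach to be retained; 0 disables
#'   the filter.
#' @param restrict_to_expressed Restrict the hypergeometric miRNA universe
#'   to miRNAs present in the miRNA expression matrix (default TRUE).
#' @return A list of class `candidate_config`.
#' @export
candidate_config <- function(hyper_alpha = 0.05, corr_alpha = 0.05,
                             percentile_cut = 90, restrict_to_expressed = TRUE) {
  stopifnot(hyper_alpha > 0, hyper_alpha < 1, corr_alpha > 0, corr_alpha < 1,
            percentile_cut >= 0, percentile_cut < 100)
  .assert_flag(restrict_to_expressed, "restrict_to_expressed")
  structure(list(hyper_alpha = hyper_alpha, corr_alpha = corr_alpha,
                 percentile_cut = percentile_cut,
                 restrict_to_expressed = restrict_to_expressed),
            class = "candidate_config")
}

#' Shared-miRNA hypergeometric test for an (mRNA, lncRNA) pair
#'
#' Tests whether an mRNA and a lncRNA share more targeting miRNAs than
#' expected by chance. With a universe of `N` distinct miRNAs having at
#' least one interaction of either kind, `K` targeting the mRNA, `n`
#' targeting the lncRNA and `k` shared, the p-value is the upper tail
#' P(X >= k) of a hypergeometric(N, K, n) distribution.
#'
#' @param mrna,lncrna Gene ids.
#' @param interactions An [interaction_set()].
#' @param universe Optional character vector overriding the miRNA universe
#'   (default: distinct miRNAs in the union of both maps).
#' @return List with `shared_count` and `hypergeom_p`.
#' @export
shared_mirna_test <- function(mrna, lncrna, interactions, universe = NULL) {
  m2m <- interactions$mirna_to_mrna
  m2l <- interactions$mirna_to_lncrna
  mir_m <- names(m2m)[vapply(m2m, function(v) mrna %in% v, logical(1L))]
  mir_l <- names(m2l)[vapply(m2l, function(v) lncrna %in% v, logical(1L))]
  if (length(mir_m) == 0L) stop("mRNA '", mrna, "' absent from interaction map")
  if (length(mir_l) == 0L) stop("lncRNA '", lncrna, "' absent from interaction map")
  universe <- universe %||% union(names(m2m), names(m2l))
  k <- length(intersect(mir_m, mir_l))
  K <- length(intersect(mir_m, universe))
  n <- length(intersect(mir_l, universe))
  N <- length(universe)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(shared_count = k, hypergeom_p = p)
}

#' Pearson correlation with a t-distribution p-value
#'
#' Two-sided p-value from t = r * sqrt(n - 2) / sqrt(1 - r^2) with n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length n >= 4 with nonzero variance.
#' @return List with `r` and `p`.
#' @export
correlation_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector: correlation undefined")
  r <- stats::cor(x, y)
  list(r = r, p = .cor_pval(r, n))
}

# Assemble the three per-class pair tables implied by an interaction set,
# with correlations computed in the given (reference-state) matrices.
.candidate_pair_tables <- function(control, interactions) {
  zm <- .standardize_rows(control$mrna$values)
  zl <- .standardize_rows(control$lncrna$values)
  zi <- .standardize_rows(control$mirna$values)
  n <- ncol(zm)

  mm <- .pairs_df(interactions$mirna_to_mrna, "mrna")
  ml <- .pairs_df(interactions$mirna_to_lncrna, "lncrna")
  mm$r <- .pair_cor(zi, zm, match(mm$mirna, rownames(zi)), match(mm$mrna, rownames(zm)))
  ml$r <- .pair_cor(zi, zl, match(ml$mirna, rownames(zi)), match(ml$lncrna, rownames(zl)))
  mm$p <- .cor_pval(mm$r, n)
  ml$p <- .cor_pval(ml$r, n)

  # all (mRNA, lncRNA) pairs sharing >= 1 miRNA, one row per shared miRNA
  lm_rows <- merge(mm[, c("mirna", "mrna")], ml[, c("mirna", "lncrna")], by = "mirna")
  if (nrow(lm_rows) == 0L) stop("no (mRNA, lncRNA) pair shares a miRNA")
  pair_key <- paste(lm_rows$mrna, lm_rows$lncrna, sep = "\r")
  lm_pairs <- lm_rows[!duplicated(pair_key), c("mrna", "lncrna")]
  lm_pairs$shared_count <- as.integer(table(pair_key)[paste(lm_pairs$mrna, lm_pairs$lncrna, sep = "\r")])
  lm_pairs$r <- .pair_cor(zl, zm, match(lm_pairs$lncrna, rownames(zl)),
                          match(lm_pairs$mrna, rownames(zm)))
  lm_pairs$p <- .cor_pval(lm_pairs$r, n)

  list(mm = mm, ml = ml, lm_rows = lm_rows, lm_pairs = lm_pairs, n = n)
}

#' Identify candidate ceRNA triplets in the reference state
#'
#' A candidate triplet (lncRNA, miRNA, mRNA) must satisfy, in the reference
#' (control) samples: (i) the mRNA and lncRNA share a significant number of
#' targeting miRNAs (hypergeometric p < `hyper_alpha`); (ii) the miRNA is
#' negatively correlated with both the mRNA and the lncRNA, the lncRNA and
#' mRNA are positively correlated, all three at p < `corr_alpha`; (iii) each
#' of the three links exceeds the `percentile_cut` percentile of the overall
#' |r| distribution of its pair class (miRNA-mRNA and miRNA-lncRNA over all
#' profiled interaction pairs; lncRNA-mRNA over all pairs sharing at least
#' one miRNA). A triplet is emitted only if all three links survive.
#'
#' @param control Named list with elements `mrna`, `lncrna`, `mirna`, each an
#'   [expression_matrix()] restricted to the same reference samples.
#' @param interactions An [interaction_set()].
#' @param config A [candidate_config()].
#' @return Data frame, one row per candidate triplet, with the shared-miRNA
#'   count, hypergeometric p, and the three (r, p) link statistics, sorted
#'   by (lncrna, mirna, mrna).
#' @export
find_candidates <- function(control, interactions, config = candidate_config()) {
  stopifnot(inherits(config, "candidate_config"))
  if (!all(c("mrna", "lncrna", "mirna") %in% names(control))) {
    stop("'control' must be a named list with mrna, lncrna, mirna matrices")
  }
  sids <- lapply(control, sample_ids)
  if (!all(vapply(sids[-1L], setequal, logical(1L), sids[[1L]]))) {
    stop("control sample ids must be identical across the three matrices")
  }
  control$lncrna <- subset_samples(control$lncrna, sids$mrna)
  control$mirna <- subset_samples(control$mirna, sids$mrna)

  interactions <- restrict_interactions(
    interactions,
    mrna_ids = gene_ids(control$mrna),
    lncrna_ids = gene_ids(control$lncrna),
    mirna_ids = if (config$restrict_to_expressed) gene_ids(control$mirna) else NULL
  )
  universe <- union(names(interactions$mirna_to_mrna), names(interactions$mirna_to_lncrna))

  tab <- .candidate_pair_tables(control, interactions)

  # class-wise |r| retention thresholds over the overall pair distributions
  pc <- config$percentile_cut / 100
  thr_mm <- stats::quantile(abs(tab$mm$r), pc, names = FALSE)
  thr_ml <- stats::quantile(abs(tab$ml$r), pc, names = FALSE)
  thr_lm <- stats::quantile(abs(tab$lm_pairs$r), pc, names = FALSE)

  # hypergeometric test per distinct (mRNA, lncRNA) pair
  K <- table(unique(tab$mm[, c("mirna", "mrna")])$mrna)
  nL <- table(unique(tab$ml[, c("mirna", "lncrna")])$lncrna)
  lm <- tab$lm_pairs
  lm$hypergeom_p <- stats::phyper(lm$shared_count - 1L,
                                  as.integer(K[lm$mrna]),
                                  length(universe) - as.integer(K[lm$mrna]),
                                  as.integer(nL[lm$lncrna]), lower.tail = FALSE)
  lm <- lm[lm$hypergeom_p < config$hyper_alpha, , drop = FALSE]
  lm <- lm[lm$r > 0 & lm$p < config$corr_alpha & abs(lm$r) >= thr_lm, , drop = FALSE]
  if (nrow(lm) == 0L) return(.empty_candidates())

  # expand to (pair, shared miRNA) rows and apply the per-link filters
  rows <- merge(tab$lm_rows, lm[, c("mrna", "lncrna", "shared_count", "hypergeom_p", "r", "p")],
                by = c("mrna", "lncrna"))
  names(rows)[names(rows) == "r"] <- "r_l_m"
  names(rows)[names(rows) == "p"] <- "p_l_m"
  mm_key <- paste(tab$mm$mirna, tab$mm$mrna, sep = "\r")
  ml_key <- paste(tab$ml$mirna, tab$ml$lncrna, sep = "\r")
  i_mm <- match(paste(rows$mirna, rows$mrna, sep = "\r"), mm_key)
  i_ml <- match(paste(rows$mirna, rows$lncrna, sep = "\r"), ml_key)
  rows$r_mi_m <- tab$mm$r[i_mm]
  rows$p_mi_m <- tab$mm$p[i_mm]
  rows$r_mi_l <- tab$ml$r[i_ml]
  rows$p_mi_l <- tab$ml$p[i_ml]

  keep <- rows$r_mi_m < 0 & rows$p_mi_m < config$corr_alpha & abs(rows$r_mi_m) >= thr_mm &
    rows$r_mi_l < 0 & rows$p_mi_l < config$corr_alpha & abs(rows$r_mi_l) >= thr_ml
  out <- rows[keep, c("lncrna", "mirna", "mrna", "shared_count", "hypergeom_p",
                      "r_mi_m", "p_mi_m", "r_mi_l", "p_mi_l", "r_l_m", "p_l_m"),
              drop = FALSE]
  names(out)[names(out) == "shared_count"] <- "shared_mirna_count"
  out <- out[order(out$lncrna, out$mirna, out$mrna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_candidates <- function() {
  data.frame(lncrna = character(), mirna = character(), mrna = character(),
             shared_mirna_count = integer(), hypergeom_p = numeric(),
             r_mi_m = numeric(), p_mi_m = numeric(),
             r_mi_l = numeric(), p_mi_l = numeric(),
             r_l_m = numeric(), p_l_m = numeric(), stringsAsFactors = FALSE)
}
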