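#' Configuration for triplet dysregulation scoring
#'
#' @param omega Weight of the node (differential expression) component in
#'   the combined score, in `[0, 1]`; the edge (differential co-expression)
#'   component gets `1 - omega`. Default 0.5 (equal weighting).
#' @param n_permutations Number of random triplets drawn for the empirical
#'   null (default 10000).
#' @param perm_alpha Empirical p-value threshold for flagging a triplet as
#'   dysregulated (default 0.05).
#' @param seed Integer seed for the permutation draw.
#' @param clamp_eps Clamp width for the tail transform (default 1e-15); the
#'   transformed probability is kept inside `[clamp_eps, 1 - clamp_eps]` so
#'   every score stays finite.
#' @param de_method Differential expression method used for node statistics
#'   (`"moderated"` or `"welch"`).
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(omega = 0.5, n_permutations = 10000L, perm_alpha = 0.05,
                           seed = 1L, clamp_eps = 1e-15,
                           de_method = c("moderated", "welch")) {
  stopifnot(omega >= 0, omega <= 1, n_permutations >= 1,
            perm_alpha > 0, perm_alpha < 1,
            clamp_eps > 0, clamp_eps < 0.5)
  structure(list(omega = omega, n_permutations = as.integer(n_permutations),
                 perm_alpha = perm_alpha, seed = as.integer(seed),
                 clamp_eps = clamp_eps, de_method = match.arg(de_method)),
            class = "scoring_config")
}

#' Standard-normal tail transform of a non-negative statistic
#'
#' Maps a non-negative statistic d onto the standard-normal quantile scale
#' via `qnorm(q)` with `q = 1 - 2 * (1 - pnorm(d))`, i.e. the two-sided
#' tail probability of d re-expressed as a quantile. `q` is clamped into
#' `[clamp_eps, 1 - clamp_eps]` (at d = 0, q is exactly 0 and would map to
#' -Inf), so the transform is finite and strictly increasing.
#'
#' @param d Non-negative numeric vector.
#' @param clamp_eps Clamp width (see [scoring_config()]).
#' @return Numeric vector of transformed scores.
#' @export
tail_transform <- function(d, clamp_eps = 1e-15) {
  if (any(d < 0)) stop("'d' must be non-negative")
  # work on the two-sided tail p2 = 1 - q so far-tail quantiles keep full
  # relative precision; clamping p2 into [eps, 1 - eps] is the same as
  # clamping q
  p2 <- 2 * stats::pnorm(d, lower.tail = FALSE)
  ifelse(p2 <= 0.5,
         -stats::qnorm(pmax(p2, clamp_eps)),       # clamp q at 1 - eps
         stats::qnorm(pmax(1 - p2, clamp_eps)))    # clamp q at eps
}

#' Node score from differential expression
#'
#' The per-transcript dysregulation statistic is
#' `D = (-log10 p) * |log2FC|`, passed through [tail_transform()].
#' P-values are floored at 1e-300 before the log.
#'
#' @param p P-value(s) in (0, 1] from a two-group differential test.
#' @param log2fc Log2 fold change(s).
#' @param clamp_eps Clamp width.
#' @return Numeric vector of node scores.
#' @export
node_score <- function(p, log2fc, clamp_eps = 1e-15) {
  if (any(p > 1) || any(p <= 0)) stop("p-values must lie in (0, 1]")
  d <- (-log10(.floor_p(p))) * abs(log2fc)
  tail_transform(d, clamp_eps)
}

#' Fisher z-transformation of a correlation coefficient
#'
#' `F(r) = 0.5 * ln((1 + r) / (1 - r))`, the variance-stabilizing
#' transform of a Pearson correlation (equal to `atanh(r)`). `|r|` is
#' clamped to `1 - 1e-7` so the transform stays finite.
#'
#' @param r Numeric vector of correlations.
#' @return Numeric vector.
#' @export
fisher_z <- function(r) {
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  0.5 * log((1 + r) / (1 - r))
}

#' Edge score from differential co-expression
#'
#' The change in a link's co-expression between two states is measured by
#' \deqn{\xi = \frac{F(r_2)(-\log_{10} p_2) - F(r_1)(-\log_{10} p_1)}
#'   {\sqrt{1/(n_2 - 3) + 1/(n_1 - 3)}}}
#' where F is the Fisher z-transform and (r, p, n) are the link's Pearson
#' correlation, its p-value and the sample count in each state. The edge
#' score is `tail_transform(|xi|)`.
#'
#' @param r1,p1,n1 Correlation, p-value and sample count in state 1
#'   (reference).
#' @param r2,p2,n2 Same for state 2.
#' @param clamp_eps Clamp width.
#' @return List with `xi` and `score` (vectors).
#' @export
edge_score <- function(r1, p1, n1, r2, p2, n2, clamp_eps = 1e-15) {
  if (any(n1 <= 3) || any(n2 <= 3)) stop("edge score needs more than 3 samples per state")
  xi <- (fisher_z(r2) * (-log10(.floor_p(p2))) - fisher_z(r1) * (-log10(.floor_p(p1)))) /
    sqrt(1 / (n2 - 3) + 1 / (n1 - 3))
  list(xi = xi, score = tail_transform(abs(xi), clamp_eps))
}

#' Combine node and edge scores for one triplet
#'
#' `Score = omega * mean(node_scores) + (1 - omega) * mean(edge_scores)`,
#' with exactly 3 node scores (lncRNA, miRNA, mRNA) and 3 edge scores
#' (miRNA-mRNA, miRNA-lncRNA, lncRNA-mRNA).
#'
#' @param node_scores,edge_scores Numeric vectors of length 3.
#' @param omega Node weight in `[0, 1]`.
#' @return Scalar combined score.
#' @export
triplet_score <- function(node_scores, edge_scores, omega = 0.5) {
  if (length(node_scores) != 3L || length(edge_scores) != 3L) {
    stop("a triplet has exactly 3 node scores and 3 edge scores")
  }
  stopifnot(omega >= 0, omega <= 1)
  omega * mean(node_scores) + (1 - omega) * mean(edge_scores)
}

#' Precompute the shared state needed to score many triplets
#'
#' Runs differential expression (state1 -> state2) for each transcript
#' class and row-standardizes each class's submatrix per state, so that
#' arbitrary link correlations reduce to row inner products.
#'
#' @param expr Named list with `mrna`, `lncrna`, `mirna`
#'   [expression_matrix()] objects covering both states.
#' @param state1_samples,state2_samples Disjoint sample-id vectors (each
#'   > 3 samples); state 1 is the reference (e.g. control), state 2 the
#'   case, fixing the sign convention of xi (only |xi| enters the score).
#' @param config A [scoring_config()].
#' @param de Optional precomputed list of differential results (named
#'   `mrna`, `lncrna`, `mirna`), as returned by
#'   [differential_expression()] with `group1 = state1_samples`.
#' @return A list of class `scoring_context`.
#' @export
scoring_context <- function(expr, state1_samples, state2_samples,
                            config = scoring_config(), de = NULL) {
  stopifnot(inherits(config, "scoring_config"))
  classes <- c("mrna", "lncrna", "mirna")
  if (!all(classes %in% names(expr))) {
    stop("'expr' must be a named list with mrna, lncrna, mirna matrices")
  }
  state1_samples <- as.character(state1_samples)
  state2_samples <- as.character(state2_samples)
  if (length(intersect(state1_samples, state2_samples)) > 0L) {
    stop("state sample sets must be disjoint")
  }
  if (length(state1_samples) <= 3L || length(state2_samples) <= 3L) {
    stop("each state needs more than 3 samples")
  }
  z1 <- list(); z2 <- list()
  if (is.null(de)) {
    de <- lapply(expr[classes], differential_expression,
                 group1 = state1_samples, group2 = state2_samples,
                 method = config$de_method)
  }
  for (cl in classes) {
    z1[[cl]] <- .standardize_rows(expr[[cl]]$values[, state1_samples, drop = FALSE])
    z2[[cl]] <- .standardize_rows(expr[[cl]]$values[, state2_samples, drop = FALSE])
  }
  structure(list(z1 = z1, z2 = z2,
                 n1 = length(state1_samples), n2 = length(state2_samples),
                 de = de[classes], config = config),
            class = "scoring_context")
}

# Vectorized scoring of triplet id vectors against a context
.score_triplet_ids <- function(ctx, lncrna, mirna, mrna, omega = NULL, clamp_eps = NULL) {
  omega <- omega %||% ctx$config$omega
  clamp_eps <- clamp_eps %||% ctx$config$clamp_eps
  lookup <- function(cl, ids) {
    de <- ctx$de[[cl]]
    i <- match(ids, de$gene_id)
    if (anyNA(i)) {
      stop("triplet gene(s) absent from ", cl, " matrix: ",
           paste(utils::head(unique(ids[is.na(i)]), 5L), collapse = ", "))
    }
    node_score(de$p_value[i], de$log2fc[i], clamp_eps)
  }
  node_l <- lookup("lncrna", lncrna)
  node_mi <- lookup("mirna", mirna)
  node_m <- lookup("mrna", mrna)

  ridx <- function(z, cl, ids) {
    i <- match(ids, rownames(z[[cl]]))
    if (anyNA(i)) {
      stop("triplet gene(s) absent from ", cl, " matrix: ",
           paste(utils::head(unique(ids[is.na(i)]), 5L), collapse = ", "))
    }
    i
  }
  il <- ridx(ctx$z1, "lncrna", lncrna)
  ii <- ridx(ctx$z1, "mirna", mirna)
  im <- ridx(ctx$z1, "mrna", mrna)
  link <- function(cla, clb, ia, ib) {
    r1 <- .pair_cor(ctx$z1[[cla]], ctx$z1[[clb]], ia, ib)
    r2 <- .pair_cor(ctx$z2[[cla]], ctx$z2[[clb]], ia, ib)
    edge_score(r1, .cor_pval(r1, ctx$n1), ctx$n1,
               r2, .cor_pval(r2, ctx$n2), ctx$n2, clamp_eps)
  }
  e_mi_m <- link("mirna", "mrna", ii, im)
  e_mi_l <- link("mirna", "lncrna", ii, il)
  e_l_m <- link("lncrna", "mrna", il, im)

  node_mean <- (node_l + node_mi + node_m) / 3
  edge_mean <- (e_mi_m$score + e_mi_l$score + e_l_m$score) / 3
  data.frame(
    lncrna = lncrna, mirna = mirna, mrna = mrna,
    node_score_lncrna = node_l, node_score_mirna = node_mi, node_score_mrna = node_m,
    xi_mi_m = e_mi_m$xi, xi_mi_l = e_mi_l$xi, xi_l_m = e_l_m$xi,
    edge_score_mi_m = e_mi_m$score, edge_score_mi_l = e_mi_l$score,
    edge_score_l_m = e_l_m$score,
    score = omega * node_mean + (1 - omega) * edge_mean,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Score candidate triplets for dysregulation between two states
#'
#' For each triplet, three node scores are computed from each member's
#' differential expression (p, log2FC) between the states, and three edge
#' scores from each link's correlation change (Fisher-z weighted by
#' -log10 p, normalized by sample sizes), then combined with weight
#' `omega` (see [triplet_score()]).
#'
#' @param candidates Data frame with columns `lncrna`, `mirna`, `mrna`
#'   (e.g. from [find_candidates()]); additional columns are preserved.
#' @param expr,state1_samples,state2_samples,config,de Passed to
#'   [scoring_context()]; alternatively supply a prebuilt context via
#'   `context`.
#' @param context Optional [scoring_context()] (overrides the other
#'   arguments).
#' @return `candidates` with node scores, xi values, edge scores and the
#'   combined `score` appended, sorted by decreasing score.
#' @export
score_candidates <- function(candidates, expr = NULL, state1_samples = NULL,
                             state2_samples = NULL, config = scoring_config(),
                             de = NULL, context = NULL) {
  if (is.null(candidates) || nrow(candidates) == 0L) stop("no candidate triplets to score")
  if (!all(c("lncrna", "mirna", "mrna") %in% names(candidates))) {
    stop("'candidates' must have columns lncrna, mirna, mrna")
  }
  ctx <- context %||% scoring_context(expr, state1_samples, state2_samples, config, de)
  scored <- .score_triplet_ids(ctx, candidates$lncrna, candidates$mirna, candidates$mrna)
  extra <- setdiff(names(candidates), names(scored))
  out <- cbind(candidates[, c("lncrna", "mirna", "mrna", extra), drop = FALSE],
               scored[, !(names(scored) %in% c("lncrna", "mirna", "mrna")), drop = FALSE])
  out <- out[order(-out$score, out$lncrna, out$mirna, out$mrna), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scoring_context") <- ctx
  out
}

#' Empirical permutation p-values for scored triplets
#'
#' Builds one shared null distribution: `n_permutations` random triplets
#' are assembled by independently drawing one lncRNA, one miRNA and one
#' mRNA from the pools and scored with the same machinery (regardless of
#' interaction support). The empirical p-value of an observed triplet is
#' the proportion of null scores strictly larger than its score; triplets
#' with p below `perm_alpha` are flagged dysregulated.
#'
#' @param scored Data frame from [score_candidates()].
#' @param context A [scoring_context()]; defaults to the one attached to
#'   `scored`.
#' @param config A [scoring_config()]; defaults to the context's.
#' @param pools Optional named list (`lncrna`, `mirna`, `mrna`) of gene-id
#'   pools; defaults to the genes appearing in `scored` (set each element
#'   to all profiled genes to widen the null).
#' @return `scored` with `empirical_p` and `dysregulated` appended; the
#'   null score vector is attached as attribute `"null_scores"`.
#' @export
permutation_pvalues <- function(scored, context = NULL, config = NULL, pools = NULL) {
  ctx <- context %||% attr(scored, "scoring_context")
  if (is.null(ctx)) stop("no scoring context available; pass 'context'")
  config <- config %||% ctx$config
  pools <- pools %||% list(lncrna = unique(scored$lncrna),
                           mirna = unique(scored$mirna),
                           mrna = unique(scored$mrna))
  if (any(lengths(pools) == 0L)) stop("empty permutation pool")
  nperm <- config$n_permutations
  set.seed(config$seed)
  draw <- function(pool) pool[sample.int(length(pool), nperm, replace = TRUE)]
  null_scores <- .score_triplet_ids(ctx, draw(pools$lncrna), draw(pools$mirna),
                                    draw(pools$mrna),
                                    omega = config$omega,
                                    clamp_eps = config$clamp_eps)$score
  sorted <- sort(null_scores)
  # strictly-greater count: n minus the number of null scores <= observed
  scored$empirical_p <- (nperm - findInterval(scored$score, sorted)) / nperm
  scored$dysregulated <- scored$empirical_p < config$perm_alpha
  attr(scored, "null_scores") <- null_scores
  scored
}

#' Traditional (unscored) dysregulated triplet identification
#'
#' The comparator criteria: (1) all three transcripts are SDE between the
#' states; (2) the mRNA and lncRNA share a significant number of miRNAs
#' (hypergeometric p < `hyper_alpha`); (3) in the reference samples the
#' miRNA-mRNA and miRNA-lncRNA links are negatively correlated and the
#' lncRNA-mRNA link positively correlated (all p < `corr_alpha`), while in
#' the case samples the lncRNA-mRNA link is no longer positive-significant
#' (r <= 0 or p >= `corr_alpha`). Returns an unscored triplet set.
#'
#' @param expr Named list with `mrna`, `lncrna`, `mirna` matrices.
#' @param control_samples,case_samples Sample-id vectors for the two states.
#' @param interactions An [interaction_set()].
#' @param sde_alpha,hyper_alpha,corr_alpha Thresholds (defaults 0.05).
#' @param de_method Differential expression method.
#' @return Data frame of triplets with link statistics in both states.
#' @export
traditional_method <- function(expr, control_samples, case_samples, interactions,
                               sde_alpha = 0.05, hyper_alpha = 0.05,
                               corr_alpha = 0.05,
                               de_method = c("moderated", "welch")) {
  de_method <- match.arg(de_method)
  control <- lapply(expr, subset_samples, samples = control_samples)
  cands <- find_candidates(control, interactions,
                           candidate_config(hyper_alpha = hyper_alpha,
                                            corr_alpha = corr_alpha,
                                            percentile_cut = 0))
  if (nrow(cands) == 0L) return(cands)

  sde <- lapply(expr[c("mrna", "lncrna", "mirna")], function(m) {
    de <- differential_expression(m, control_samples, case_samples,
                                  method = de_method, sde_alpha = sde_alpha)
    de$gene_id[de$is_sde]
  })
  keep_sde <- cands$mrna %in% sde$mrna & cands$lncrna %in% sde$lncrna &
    cands$mirna %in% sde$mirna
  cands <- cands[keep_sde, , drop = FALSE]
  if (nrow(cands) == 0L) return(cands)

  zl <- .standardize_rows(expr$lncrna$values[, case_samples, drop = FALSE])
  zm <- .standardize_rows(expr$mrna$values[, case_samples, drop = FALSE])
  r_case <- .pair_cor(zl, zm, match(cands$lncrna, rownames(zl)),
                      match(cands$mrna, rownames(zm)))
  p_case <- .cor_pval(r_case, length(case_samples))
  cands$r_l_m_case <- r_case
  cands$p_l_m_case <- p_case
  out <- cands[!(r_case > 0 & p_case < corr_alpha), , drop = FALSE]
  rownames(out) <- NULL
  out
}
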