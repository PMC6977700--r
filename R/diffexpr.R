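#' Two-group differential expression on log2 data
#'
#' Computes per-gene log2 fold change (group2 mean minus group1 mean on the
#' already-log2 data) and a two-sided p-value. `"moderated"` uses the
#' empirical-Bayes moderated t-statistic (per-gene variances shrunk toward a
#' pooled prior, via limma); `"welch"` is a plain unequal-variance t-test.
#' Genes with raw p below `sde_alpha` are flagged as significantly
#' differentially expressed (SDE); no multiple-testing correction is applied
#' to the call, but a BH-FDR column is emitted for information.
#'
#' @param expr An [expression_matrix()].
#' @param group1,group2 Disjoint character vectors of sample ids, each of
#'   size >= 2. `group1` is the reference: positive `log2fc` means higher
#'   expression in `group2`.
#' @param method `"moderated"` (default) or `"welch"`.
#' @param sde_alpha Raw p-value threshold for the SDE call (default 0.05).
#' @return Data frame with columns `gene_id`, `log2fc`, `p_value`, `fdr`,
#'   `is_sde`, `direction` (`up`/`down`/`flat`). P-values are floored at
#'   1e-300 so that downstream -log10 transforms stay finite.
#' @export
differential_expression <- function(expr, group1, group2,
                                    method = c("moderated", "welch"),
                                    sde_alpha = 0.05) {
  method <- match.arg(method)
  group1 <- as.character(group1)
  group2 <- as.character(group2)
  sids <- sample_ids(expr)
  if (!all(group1 %in% sids) || !all(group2 %in% sids)) {
    stop("group samples must be columns of the expression matrix")
  }
  if (length(intersect(group1, group2)) > 0L) stop("groups must be disjoint")
  if (length(group1) < 2L || length(group2) < 2L) {
    stop("each group needs at least 2 samples")
  }
  x <- expr$values[, c(group1, group2), drop = FALSE]
  n1 <- length(group1)
  n2 <- length(group2)

  if (method == "moderated") {
    grp <- factor(rep(c("g1", "g2"), c(n1, n2)), levels = c("g1", "g2"))
    design <- stats::model.matrix(~grp)
    fit <- limma::eBayes(limma::lmFit(x, design))
    lfc <- fit$coefficients[, 2L]
    p <- fit$p.value[, 2L]
  } else {
    x1 <- x[, seq_len(n1), drop = FALSE]
    x2 <- x[, n1 + seq_len(n2), drop = FALSE]
    m1 <- rowMeans(x1)
    m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
    se2 <- v1 / n1 + v2 / n2
    lfc <- m2 - m1
    tt <- lfc / sqrt(se2)
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
    p <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
    # zero within-group variance: equal means are unremarkable, unequal means decisive
    degenerate <- se2 == 0
    p[degenerate] <- ifelse(lfc[degenerate] == 0, 1, 0)
  }
  p[is.na(p)] <- 1
  p <- .floor_p(pmin(p, 1))
  # least-squares round-off on genes with exactly equal group means must not
  # masquerade as a direction
  lfc[abs(lfc) < 1e-12] <- 0
  data.frame(
    gene_id = rownames(x),
    log2fc = unname(lfc),
    p_value = unname(p),
    fdr = stats::p.adjust(p, method = "BH"),
    is_sde = unname(p < sde_alpha),
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "flat")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Summarize SDE fractions and up/down split
#'
#' @param results Data frame from [differential_expression()].
#' @return List with `pct_sde` (percent of all genes called SDE),
#'   `pct_up_among_sde` and `pct_down_among_sde` (percent of SDE genes up-
#'   or downregulated; `NA` when no gene is SDE). All on a 0-100 scale.
#' @export
sde_direction_summary <- function(results) {
  if (is.null(results) || nrow(results) == 0L) stop("empty differential result")
  sde <- results[results$is_sde, , drop = FALSE]
  list(
    pct_sde = 100 * nrow(sde) / nrow(results),
    pct_up_among_sde = if (nrow(sde)) 100 * mean(sde$direction == "up") else NA_real_,
    pct_down_among_sde = if (nrow(sde)) 100 * mean(sde$direction == "down") else NA_real_
  )
}

#' Genes differentially expressed across every adjacent stage transition
#'
#' Runs [differential_expression()] for each pair of consecutive sample
#' groups (S0 vs S1, S1 vs S2, ...) and returns the genes called SDE in all
#' transitions.
#'
#' @param expr An [expression_matrix()].
#' @param ordered_groups List (length >= 2) of sample-id vectors in stage
#'   order.
#' @param method,sde_alpha Passed to [differential_expression()].
#' @return Character vector of gene ids.
#' @export
always_sde_genes <- function(expr, ordered_groups,
                             method = c("moderated", "welch"), sde_alpha = 0.05) {
  method <- match.arg(method)
  if (length(ordered_groups) < 2L) stop("need at least 2 ordered groups")
  sets <- lapply(seq_len(length(ordered_groups) - 1L), function(i) {
    de <- differential_expression(expr, ordered_groups[[i]], ordered_groups[[i + 1L]],
                                  method = method, sde_alpha = sde_alpha)
    de$gene_id[de$is_sde]
  })
  Reduce(intersect, sets)
}
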