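#' Generate a sample-matched synthetic ceRNA cohort
#'
#' Emulates the structure of a two-state (control vs case) cohort profiled
#' for mRNAs, lncRNAs and miRNAs on a log2 scale, with planted ceRNA
#' triplets. In control samples each planted triplet follows a latent
#' factor L per sample: mRNA and lncRNA load positively on L, the miRNA
#' negatively, so the ceRNA sign pattern (miRNA-target links negative,
#' lncRNA-mRNA link positive) holds by construction with pairwise
#' correlation `rho`. In case samples, dysregulated triplets lose the
#' latent coupling (independent noise of matched marginal variance) and
#' their members are mean-shifted by `delta` (mRNA and lncRNA up, miRNA
#' down); intact planted triplets keep the control structure. Background
#' genes are independent noise. The interaction table contains both links
#' of every planted triplet plus `n_decoy` random decoy pairs per link
#' class among background genes (planted genes receive no decoy edges, so
#' the planted shared-miRNA structure is unambiguous).
#'
#' @param n_control,n_case Sample counts (defaults 46 and 73).
#' @param n_mrna,n_lncrna,n_mirna Gene counts per class (defaults 200, 60,
#'   40).
#' @param n_triplets Number of planted triplets (default 20; needs one
#'   distinct gene of each class per triplet).
#' @param n_dysregulated How many planted triplets are decoupled and
#'   shifted in cases (default: all of them).
#' @param rho Latent pairwise correlation strength of planted links in
#'   (0, 1) (default 0.9).
#' @param delta Log2 mean shift of dysregulated members in cases
#'   (default 1).
#' @param sigma Residual noise sd in log2 units (default 0.3); planted
#'   genes have total sd `sigma / sqrt(1 - rho)`, matched by background
#'   genes.
#' @param n_decoy Decoy interaction pairs per link class (default 300).
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @return List of class `synthetic_cohort`: `expr` (list of three
#'   [expression_matrix()]), `metadata`, `interactions`, `truth` (planted
#'   triplets with `is_dysregulated`), `params`.
#' @export
generate_cohort <- function(n_control = 46L, n_case = 73L,
                            n_mrna = 200L, n_lncrna = 60L, n_mirna = 40L,
                            n_triplets = 20L, n_dysregulated = n_triplets,
                            rho = 0.9, delta = 1, sigma = 0.3,
                            n_decoy = 300L, seed = 1L) {
  stopifnot(n_control >= 4L, n_case >= 4L, n_mrna >= 1L, n_lncrna >= 1L,
            n_mirna >= 1L, n_triplets >= 0L, rho > 0, rho < 1, sigma > 0,
            n_dysregulated >= 0L, n_dysregulated <= n_triplets)
  if (n_triplets > min(n_mrna, n_lncrna, n_mirna)) {
    stop("n_triplets exceeds the smallest gene-class count")
  }
  set.seed(seed)
  a <- sigma * sqrt(rho / (1 - rho)) # latent loading giving pairwise cor rho
  s_tot <- sqrt(a^2 + sigma^2)
  ids <- list(mrna = sprintf("G%04d", seq_len(n_mrna)),
              lncrna = sprintf("LNC%03d", seq_len(n_lncrna)),
              mirna = sprintf("MIR%03d", seq_len(n_mirna)))
  samples <- c(sprintf("CTRL%03d", seq_len(n_control)),
               sprintf("CASE%03d", seq_len(n_case)))
  ctrl_idx <- seq_len(n_control)
  case_idx <- n_control + seq_len(n_case)
  n_all <- n_control + n_case

  base <- list(mrna = stats::runif(n_mrna, 6, 12),
               lncrna = stats::runif(n_lncrna, 4, 8),
               mirna = stats::runif(n_mirna, 2, 6))
  vals <- lapply(c(mrna = "mrna", lncrna = "lncrna", mirna = "mirna"), function(cl) {
    m <- matrix(stats::rnorm(length(ids[[cl]]) * n_all, 0, s_tot),
                nrow = length(ids[[cl]])) + base[[cl]]
    dimnames(m) <- list(ids[[cl]], samples)
    m
  })

  dysregulated <- seq_len(n_triplets) <= n_dysregulated
  if (n_triplets > 0L) {
    L_ctrl <- matrix(stats::rnorm(n_triplets * n_control), n_triplets)
    L_case <- matrix(stats::rnorm(n_triplets * n_case), n_triplets)
    noise <- function(n) stats::rnorm(n, 0, sigma)
    for (t in seq_len(n_triplets)) {
      vals$mrna[t, ctrl_idx] <- base$mrna[t] + a * L_ctrl[t, ] + noise(n_control)
      vals$lncrna[t, ctrl_idx] <- base$lncrna[t] + a * L_ctrl[t, ] + noise(n_control)
      vals$mirna[t, ctrl_idx] <- base$mirna[t] - a * L_ctrl[t, ] + noise(n_control)
      if (dysregulated[t]) {
        vals$mrna[t, case_idx] <- base$mrna[t] + delta + stats::rnorm(n_case, 0, s_tot)
        vals$lncrna[t, case_idx] <- base$lncrna[t] + delta + stats::rnorm(n_case, 0, s_tot)
        vals$mirna[t, case_idx] <- base$mirna[t] - delta + stats::rnorm(n_case, 0, s_tot)
      } else {
        vals$mrna[t, case_idx] <- base$mrna[t] + a * L_case[t, ] + noise(n_case)
        vals$lncrna[t, case_idx] <- base$lncrna[t] + a * L_case[t, ] + noise(n_case)
        vals$mirna[t, case_idx] <- base$mirna[t] - a * L_case[t, ] + noise(n_case)
      }
    }
  }

  interactions <- .planted_interactions(ids, n_triplets, n_decoy)
  truth <- data.frame(lncrna = ids$lncrna[seq_len(n_triplets)],
                      mirna = ids$mirna[seq_len(n_triplets)],
                      mrna = ids$mrna[seq_len(n_triplets)],
                      is_dysregulated = dysregulated, stringsAsFactors = FALSE)
  metadata <- data.frame(sample_id = samples,
                         group = rep(c("control", "case"), c(n_control, n_case)),
                         outcome = NA_character_, stringsAsFactors = FALSE)
  structure(list(
    expr = list(mrna = expression_matrix(vals$mrna, "mRNA"),
                lncrna = expression_matrix(vals$lncrna, "lncRNA"),
                mirna = expression_matrix(vals$mirna, "miRNA")),
    metadata = metadata, interactions = interactions, truth = truth,
    params = list(n_control = n_control, n_case = n_case, n_mrna = n_mrna,
                  n_lncrna = n_lncrna, n_mirna = n_mirna,
                  n_triplets = n_triplets, n_dysregulated = n_dysregulated,
                  rho = rho, delta = delta, sigma = sigma,
                  n_decoy = n_decoy, seed = seed)
  ), class = "synthetic_cohort")
}

# planted edges (miRNA_t -> mRNA_t, miRNA_t -> lncRNA_t) plus decoys among
# background genes; decoy miRNAs may be any miRNA
.planted_interactions <- function(ids, n_triplets, n_decoy) {
  mm <- data.frame(mirna = ids$mirna[seq_len(n_triplets)],
                   target = ids$mrna[seq_len(n_triplets)], stringsAsFactors = FALSE)
  ml <- data.frame(mirna = ids$mirna[seq_len(n_triplets)],
                   target = ids$lncrna[seq_len(n_triplets)], stringsAsFactors = FALSE)
  decoy <- function(targets) {
    bg <- targets[-seq_len(n_triplets)]
    if (n_decoy == 0L || length(bg) == 0L) {
      return(data.frame(mirna = character(), target = character(),
                        stringsAsFactors = FALSE))
    }
    unique(data.frame(mirna = sample(ids$mirna, n_decoy, replace = TRUE),
                      target = sample(bg, n_decoy, replace = TRUE),
                      stringsAsFactors = FALSE))
  }
  mm <- rbind(mm, decoy(ids$mrna))
  ml <- rbind(ml, decoy(ids$lncrna))
  interaction_set(split(mm$target, mm$mirna), split(ml$target, ml$mirna))
}

#' Generate a staged (time-course) synthetic cohort
#'
#' Extends [generate_cohort()] to a control group plus `n_stages` case
#' stages (one independent sample set per stage, emulating repeated
#' profiling over disease progression). Planted triplet members follow a
#' spike-and-decay stage trajectory: the mean shift at stage s is
#' `trend_delta * w[s]` with weights `w = (1, 0.4, 0.8, 0.2)` (recycled),
#' positive for mRNA/lncRNA and negative for the miRNA; triplets alternate
#' between two trend families (the second family has all signs flipped),
#' which supports trend-clustering tests. Latent coupling is kept in the
#' control group and every stage except `dysreg_stage`, where dysregulated
#' triplets are decoupled — so that stage shows the strongest
#' triplet-level dysregulation signal.
#'
#' @param n_control Samples in the control group (default 46).
#' @param n_per_stage Case samples per stage (default 73).
#' @param n_stages Number of case stages (>= 2, default 4).
#' @param n_mrna,n_lncrna,n_mirna,n_triplets,n_dysregulated,rho,sigma,n_decoy,seed
#'   As in [generate_cohort()].
#' @param trend_delta Amplitude of the stage trajectory in log2 units
#'   (default 2).
#' @param stage_weights Optional numeric vector of per-stage trajectory
#'   weights overriding the default spike-and-decay shape (recycled to
#'   `n_stages`).
#' @param dysreg_stage Stage (1-based) at which dysregulated triplets are
#'   decoupled (default 1).
#' @return A `synthetic_cohort` whose metadata groups are `"control"`,
#'   `"S1"`, ..., and whose truth table adds a `family` column.
#' @export
generate_stages <- function(n_control = 46L, n_per_stage = 73L, n_stages = 4L,
                            n_mrna = 200L, n_lncrna = 60L, n_mirna = 40L,
                            n_triplets = 20L, n_dysregulated = n_triplets,
                            rho = 0.9, trend_delta = 2, sigma = 0.3,
                            n_decoy = 300L, dysreg_stage = 1L,
                            stage_weights = NULL, seed = 1L) {
  stopifnot(n_stages >= 2L, dysreg_stage >= 1L, dysreg_stage <= n_stages,
            rho > 0, rho < 1, sigma > 0,
            n_dysregulated >= 0L, n_dysregulated <= n_triplets)
  if (n_triplets > min(n_mrna, n_lncrna, n_mirna)) {
    stop("n_triplets exceeds the smallest gene-class count")
  }
  set.seed(seed)
  a <- sigma * sqrt(rho / (1 - rho))
  s_tot <- sqrt(a^2 + sigma^2)
  w <- rep_len(stage_weights %||% c(1, 0.4, 0.8, 0.2), n_stages)
  ids <- list(mrna = sprintf("G%04d", seq_len(n_mrna)),
              lncrna = sprintf("LNC%03d", seq_len(n_lncrna)),
              mirna = sprintf("MIR%03d", seq_len(n_mirna)))
  stage_labels <- paste0("S", seq_len(n_stages))
  samples <- c(sprintf("CTRL%03d", seq_len(n_control)),
               unlist(lapply(stage_labels, function(s)
                 sprintf("%sP%03d", s, seq_len(n_per_stage)))))
  groups <- rep(c("control", stage_labels), c(n_control, rep(n_per_stage, n_stages)))
  n_all <- length(samples)

  base <- list(mrna = stats::runif(n_mrna, 6, 12),
               lncrna = stats::runif(n_lncrna, 4, 8),
               mirna = stats::runif(n_mirna, 2, 6))
  vals <- lapply(c(mrna = "mrna", lncrna = "lncrna", mirna = "mirna"), function(cl) {
    m <- matrix(stats::rnorm(length(ids[[cl]]) * n_all, 0, s_tot),
                nrow = length(ids[[cl]])) + base[[cl]]
    dimnames(m) <- list(ids[[cl]], samples)
    m
  })

  dysregulated <- seq_len(n_triplets) <= n_dysregulated
  family <- rep_len(c(1L, 2L), n_triplets)
  group_idx <- split(seq_len(n_all), factor(groups, levels = c("control", stage_labels)))
  for (t in seq_len(n_triplets)) {
    fsign <- if (family[t] == 1L) 1 else -1
    for (g in seq_along(group_idx)) {
      idx <- group_idx[[g]]
      shift <- if (g == 1L) 0 else fsign * trend_delta * w[g - 1L]
      decouple <- g > 1L && dysregulated[t] && (g - 1L) == dysreg_stage
      if (decouple) {
        vals$mrna[t, idx] <- base$mrna[t] + shift + stats::rnorm(length(idx), 0, s_tot)
        vals$lncrna[t, idx] <- base$lncrna[t] + shift + stats::rnorm(length(idx), 0, s_tot)
        vals$mirna[t, idx] <- base$mirna[t] - shift + stats::rnorm(length(idx), 0, s_tot)
      } else {
        L <- stats::rnorm(length(idx))
        vals$mrna[t, idx] <- base$mrna[t] + shift + a * L + stats::rnorm(length(idx), 0, sigma)
        vals$lncrna[t, idx] <- base$lncrna[t] + shift + a * L + stats::rnorm(length(idx), 0, sigma)
        vals$mirna[t, idx] <- base$mirna[t] - shift - a * L + stats::rnorm(length(idx), 0, sigma)
      }
    }
  }

  interactions <- .planted_interactions(ids, n_triplets, n_decoy)
  truth <- data.frame(lncrna = ids$lncrna[seq_len(n_triplets)],
                      mirna = ids$mirna[seq_len(n_triplets)],
                      mrna = ids$mrna[seq_len(n_triplets)],
                      is_dysregulated = dysregulated, family = family,
                      stringsAsFactors = FALSE)
  metadata <- data.frame(sample_id = samples, group = groups,
                         outcome = NA_character_, stringsAsFactors = FALSE)
  structure(list(
    expr = list(mrna = expression_matrix(vals$mrna, "mRNA"),
                lncrna = expression_matrix(vals$lncrna, "lncRNA"),
                mirna = expression_matrix(vals$mirna, "miRNA")),
    metadata = metadata, interactions = interactions, truth = truth,
    params = list(n_control = n_control, n_per_stage = n_per_stage,
                  n_stages = n_stages, n_mrna = n_mrna, n_lncrna = n_lncrna,
                  n_mirna = n_mirna, n_triplets = n_triplets,
                  n_dysregulated = n_dysregulated, rho = rho,
                  trend_delta = trend_delta, stage_weights = w, sigma = sigma,
                  n_decoy = n_decoy, dysreg_stage = dysreg_stage, seed = seed)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d/%d/%d mRNA/lncRNA/miRNA genes, %d samples, %d planted triplets (%d dysregulated)\n",
              nrow(x$expr$mrna$values), nrow(x$expr$lncrna$values),
              nrow(x$expr$mirna$values), nrow(x$metadata),
              nrow(x$truth), sum(x$truth$is_dysregulated)))
  invisible(x)
}

#' Write a synthetic cohort to a directory of delimited text files
#'
#' Emits `mrna.tsv`, `lncrna.tsv`, `mirna.tsv`, `metadata.tsv`,
#' `interactions_mrna.tsv`, `interactions_lncrna.tsv` and `truth.tsv` in
#' the formats the package readers accept.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expr$mrna, file.path(dir, "mrna.tsv"))
  write_expression(cohort$expr$lncrna, file.path(dir, "lncrna.tsv"))
  write_expression(cohort$expr$mirna, file.path(dir, "mirna.tsv"))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  wr_pairs <- function(m, path) {
    df <- .pairs_df(m, "target")
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr_pairs(cohort$interactions$mirna_to_mrna, file.path(dir, "interactions_mrna.tsv"))
  wr_pairs(cohort$interactions$mirna_to_lncrna, file.path(dir, "interactions_lncrna.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return List with `expr`, `metadata`, `interactions` (and `truth` when
#'   present).
#' @export
read_cohort <- function(dir) {
  expr <- list(mrna = read_expression(file.path(dir, "mrna.tsv"), "mRNA", verbose = FALSE),
               lncrna = read_expression(file.path(dir, "lncrna.tsv"), "lncRNA", verbose = FALSE),
               mirna = read_expression(file.path(dir, "mirna.tsv"), "miRNA", verbose = FALSE))
  metadata <- read_metadata(file.path(dir, "metadata.tsv"))
  interactions <- read_interactions(file.path(dir, "interactions_mrna.tsv"),
                                    file.path(dir, "interactions_lncrna.tsv"),
                                    verbose = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    utils::read.table(truth_path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  list(expr = expr, metadata = metadata, interactions = interactions, truth = truth)
}
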