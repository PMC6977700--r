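.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.triplet_summary <- function(triplets, dysregulated = NULL) {
  sel <- if (is.null(dysregulated)) triplets else triplets[dysregulated, , drop = FALSE]
  data.frame(
    n_triplets = nrow(sel),
    n_mrna = length(unique(sel$mrna)),
    n_lncrna = length(unique(sel$lncrna)),
    n_mirna = length(unique(sel$mirna))
  )
}

#' Run the discovery workflow: candidates, scoring, permutation test
#'
#' Chains [find_candidates()] (reference state), [score_candidates()]
#' (reference vs case) and [permutation_pvalues()], writes all result
#' tables plus a JSON manifest recording every parameter and seed, and
#' logs summary counts (triplets and unique members per class).
#'
#' @param expr Named list with `mrna`, `lncrna`, `mirna`
#'   [expression_matrix()] objects.
#' @param metadata Metadata data frame (see [read_metadata()]).
#' @param interactions An [interaction_set()].
#' @param outdir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param control_group,case_group Group labels in `metadata` defining the
#'   two states.
#' @param candidate_cfg A [candidate_config()].
#' @param scoring_cfg A [scoring_config()].
#' @param null_pools `"candidates"` (default) draws permutation triplets
#'   from the genes in candidate triplets; `"all"` from all profiled genes.
#' @param run_traditional Also run [traditional_method()] side by side.
#' @param verbose Log progress.
#' @return List with `candidates`, `scored`, `summary`, `manifest` (and
#'   `traditional` if requested), invisibly.
#' @export
run_discovery <- function(expr, metadata, interactions, outdir = NULL,
                          control_group = "control", case_group = "case",
                          candidate_cfg = candidate_config(),
                          scoring_cfg = scoring_config(),
                          null_pools = c("candidates", "all"),
                          run_traditional = FALSE, verbose = TRUE) {
  null_pools <- match.arg(null_pools)
  matched <- intersect_samples(expr, metadata)
  expr <- matched$expr
  metadata <- matched$metadata
  for (g in c(control_group, case_group)) {
    if (!g %in% metadata$group) stop("group label absent from metadata: ", g)
  }
  ctrl <- metadata$sample_id[metadata$group == control_group]
  case <- metadata$sample_id[metadata$group == case_group]

  control_expr <- lapply(expr, subset_samples, samples = ctrl)
  candidates <- find_candidates(control_expr, interactions, candidate_cfg)
  if (verbose) message(sprintf("candidates: %d triplets", nrow(candidates)))
  if (nrow(candidates) == 0L) stop("discovery aborted at candidates: no candidate triplets found")

  ctx <- scoring_context(expr, ctrl, case, scoring_cfg)
  scored <- score_candidates(candidates, context = ctx)
  pools <- if (null_pools == "all") {
    list(lncrna = gene_ids(expr$lncrna), mirna = gene_ids(expr$mirna),
         mrna = gene_ids(expr$mrna))
  }
  scored <- permutation_pvalues(scored, context = ctx, config = scoring_cfg,
                                pools = pools)
  summary_tab <- cbind(
    comparison = paste0(control_group, "_vs_", case_group),
    .triplet_summary(scored, scored$dysregulated)
  )
  if (verbose) {
    message(sprintf("dysregulated: %d triplets (%d mRNAs, %d lncRNAs, %d miRNAs)",
                    summary_tab$n_triplets, summary_tab$n_mrna,
                    summary_tab$n_lncrna, summary_tab$n_mirna))
  }

  manifest <- list(
    package = "ceRNAdys",
    version = as.character(utils::packageVersion("ceRNAdys")),
    control_group = control_group, case_group = case_group,
    n_control = length(ctrl), n_case = length(case),
    candidate_config = unclass(candidate_cfg),
    scoring_config = unclass(scoring_cfg),
    null_pools = null_pools,
    n_candidates = nrow(candidates),
    n_dysregulated = sum(scored$dysregulated)
  )
  out <- list(candidates = candidates, scored = scored,
              summary = summary_tab, manifest = manifest)
  if (run_traditional) {
    out$traditional <- traditional_method(expr, ctrl, case, interactions,
                                          sde_alpha = 0.05,
                                          hyper_alpha = candidate_cfg$hyper_alpha,
                                          corr_alpha = candidate_cfg$corr_alpha,
                                          de_method = scoring_cfg$de_method)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(candidates, file.path(outdir, "candidates.tsv"))
    scored_out <- scored
    attr(scored_out, "scoring_context") <- NULL
    attr(scored_out, "null_scores") <- NULL
    .write_tsv(scored_out, file.path(outdir, "scored_triplets.tsv"))
    .write_tsv(summary_tab, file.path(outdir, "summary.tsv"))
    if (!is.null(out$traditional)) {
      .write_tsv(out$traditional, file.path(outdir, "traditional_triplets.tsv"))
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' Run the progression workflow over ordered stages
#'
#' Executes [run_discovery()] for each transition — either the reference
#' group against every stage (`mode = "control_vs_stage"`, default) or
#' each adjacent stage pair (`mode = "adjacent"`) — and derives
#' stage-specific members: lncRNAs/miRNAs appearing in one stage's
#' dysregulated triplets and no other stage's.
#'
#' @param expr,metadata,interactions,candidate_cfg,scoring_cfg,outdir As in
#'   [run_discovery()].
#' @param ordered_stages Character vector of stage labels in order.
#' @param control_group Reference group label (default `"control"`).
#' @param mode `"control_vs_stage"` or `"adjacent"`.
#' @param verbose Log per-stage counts.
#' @return List with `per_transition` (named list of [run_discovery()]
#'   results), `summary` (per-transition counts), and `stage_specific`
#'   (stage-exclusive lncRNA/miRNA members), invisibly.
#' @export
run_progression <- function(expr, metadata, interactions, ordered_stages,
                            outdir = NULL, control_group = "control",
                            mode = c("control_vs_stage", "adjacent"),
                            candidate_cfg = candidate_config(),
                            scoring_cfg = scoring_config(), verbose = TRUE) {
  mode <- match.arg(mode)
  if (length(ordered_stages) < 2L && mode == "adjacent") {
    stop("adjacent mode needs at least 2 stages")
  }
  unknown <- setdiff(c(control_group, ordered_stages), unique(metadata$group))
  if (length(unknown)) stop("unknown stage label(s): ", paste(unknown, collapse = ", "))

  transitions <- if (mode == "control_vs_stage") {
    lapply(ordered_stages, function(s) c(control_group, s))
  } else {
    lapply(seq_len(length(ordered_stages) - 1L), function(i) {
      c(ordered_stages[i], ordered_stages[i + 1L])
    })
  }
  names(transitions) <- vapply(transitions, paste, character(1L), collapse = "_vs_")

  per <- lapply(names(transitions), function(nm) {
    tr <- transitions[[nm]]
    sub <- if (is.null(outdir)) NULL else file.path(outdir, nm)
    run_discovery(expr, metadata, interactions, outdir = sub,
                  control_group = tr[1L], case_group = tr[2L],
                  candidate_cfg = candidate_cfg, scoring_cfg = scoring_cfg,
                  verbose = verbose)
  })
  names(per) <- names(transitions)

  summary_tab <- do.call(rbind, lapply(per, `[[`, "summary"))
  rownames(summary_tab) <- NULL

  # stage label for each transition = its case-side stage
  stage_of <- vapply(transitions, `[`, character(1L), 2L)
  members <- function(col) {
    sets <- lapply(per, function(r) {
      unique(r$scored[[col]][r$scored$dysregulated])
    })
    names(sets) <- stage_of
    lapply(stage_of, function(s) {
      setdiff(sets[[s]], unique(unlist(sets[names(sets) != s])))
    })
  }
  stage_specific <- list(lncrna = members("lncrna"), mirna = members("mirna"))
  names(stage_specific$lncrna) <- stage_of
  names(stage_specific$mirna) <- stage_of

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(summary_tab, file.path(outdir, "progression_summary.tsv"))
    ss <- do.call(rbind, lapply(c("lncrna", "mirna"), function(cl) {
      do.call(rbind, lapply(names(stage_specific[[cl]]), function(s) {
        ids <- stage_specific[[cl]][[s]]
        if (length(ids) == 0L) return(NULL)
        data.frame(stage = s, class = cl, gene_id = ids, stringsAsFactors = FALSE)
      }))
    }))
    if (is.null(ss)) {
      ss <- data.frame(stage = character(), class = character(),
                       gene_id = character(), stringsAsFactors = FALSE)
    }
    .write_tsv(ss, file.path(outdir, "stage_specific_members.tsv"))
  }
  invisible(list(per_transition = per, summary = summary_tab,
                 stage_specific = stage_specific))
}
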