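# Small shared synthetic cohorts, built once per test run.

tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(n_control = 30L, n_case = 30L, n_mrna = 80L,
                                n_lncrna = 40L, n_mirna = 40L, n_triplets = 6L,
                                n_dysregulated = 3L, rho = 0.9, delta = 1,
                                sigma = 0.3, n_decoy = 150L, seed = 11L)
    }
    cache
  }
})

tiny_staged <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_stages(n_control = 20L, n_per_stage = 20L, n_stages = 4L,
                                n_mrna = 60L, n_lncrna = 16L, n_mirna = 40L,
                                n_triplets = 6L, n_dysregulated = 3L, rho = 0.9,
                                trend_delta = 3.5, sigma = 0.3, n_decoy = 150L,
                                dysreg_stage = 1L, seed = 3L)
    }
    cache
  }
})

group_samples <- function(cohort, group) {
  cohort$metadata$sample_id[cohort$metadata$group == group]
}

triplet_key <- function(df) paste(df$lncrna, df$mirna, df$mrna)

# deterministic toy expression matrix
toy_expr <- function(n_genes = 5L, n_samples = 6L, prefix = "g",
                     transcript_class = "mRNA", seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes,
              dimnames = list(paste0(prefix, seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  expression_matrix(m, transcript_class)
}
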