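# Shared fixtures, memoized so expensive cohorts/fits are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

default_cohort <- function(seed = 101) {
  key <- paste0("coh", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_cohort(sim_config(seed = seed))
  .fixture_cache[[key]]
}

default_fit <- function(seed = 101) {
  key <- paste0("fit", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- immage(default_cohort(seed)$panels)
  .fixture_cache[[key]]
}

# A valid single panel with optional named overrides.
make_panel <- function(...) {
  base <- c(tcell_of_lymphs = 65, bcell_of_lymphs = 10,
            cd4_of_t = 55, cd8_of_t = 32,
            cd4_naive = 40, cd4_cm = 25, cd4_em = 20, cd4_emra = 15,
            cd8_naive = 40, cd8_cm = 15, cd8_em = 25, cd8_emra = 20,
            cd4_cd28neg = 8, cd4_cd57pos = 6, cd4_senescent = 4,
            cd8_cd28neg = 20, cd8_cd57pos = 15, cd8_senescent = 10,
            rte_of_naive_cd4 = 20, treg_of_cd4 = 5,
            b_naive = 60, b_switched_mem = 20, b_unswitched_mem = 12,
            breg_of_b = 6)
  ov <- c(...)
  base[names(ov)] <- ov
  base
}

# Ten samples equally spaced along one direction in standardized 8-D space;
# sample ids sort with position so the analytic ordering is unambiguous.
collinear_points <- function(n = 10, d = 8) {
  u <- rep(1, d) / sqrt(d)
  X <- outer(seq(0, n - 1), u)
  rownames(X) <- sprintf("S%02d", seq_len(n))
  X
}
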