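# shared fixtures built in code; cached so expensive cohorts are generated
# once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small, quick cohort for unit tests
small_spec <- function(n_subjects = 6, duration_s = 40, seed = 1, ...) {
  cohort_spec(n_subjects = n_subjects, duration_s = duration_s,
              seed = seed, ...)
}

noise_free_spec <- function(...) {
  small_spec(baseline_wander_amp = 0, powerline_amp = 0, broadband_sd = 0, ...)
}

small_cohort <- function() cached("small_cohort", generate_cohort(small_spec()))

# per-subject cycle-set lists for a cohort
session_sets <- function(cohort, session, k, normalize) {
  lapply(cohort_session(cohort, session), extract_cycle_templates,
         k = k, normalize = normalize)
}

# a deterministic, clearly non-trivial magnitude matrix for image tests
demo_scalogram <- function() {
  cached("demo_scalogram", {
    coh <- small_cohort()
    cset <- extract_cycle_templates(coh$records[[1]], k = 5, normalize = FALSE)
    compute_scalogram(cset$cycles[[1]], coh$records[[1]]$fs)
  })
}

# toy independent sources for ICA recovery checks
toy_sources <- function(n = 2000, seed = 101) {
  set.seed(seed)
  tt <- seq(0, 20, length.out = n)
  rbind(sin(2 * pi * 1.3 * tt),
        sign(sin(2 * pi * 0.61 * tt)),
        stats::runif(n, -1, 1))
}

# greedy component-to-source matching, returns best |correlation| per source
match_correlations <- function(S_est, S_true) {
  cc <- abs(stats::cor(t(S_est), t(S_true)))
  apply(cc, 2, max)
}
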