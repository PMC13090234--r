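# Shared reduced-scale study runs for the acceptance suite. Computed once
# per test session on first use (several criteria read the same datasets).

.study_cache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (is.null(.study_cache[[key]])) .study_cache[[key]] <- force(expr)
  .study_cache[[key]]
}

cached_structural_study <- function() {
  .cached("structural", run_structural_bias_study(ages = c(5, 30), n_trees = 5000, seed = 2026))
}

cached_yule_study <- function() {
  .cached("yule", run_yule_validation(n_points = 30000, seed = 2026,
                                      symreg = TRUE))
}

cached_bd_study <- function() {
  .cached("bd", run_bd_study(n_points = 20000, seed = 2026, symreg = TRUE))
}
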