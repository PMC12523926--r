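# Shared fixture builders; everything is generated in code under fixed seeds.

tiny_sim_config <- function(...) {
  sim_config(
    n_participants = 2,
    trials_per_task = c(threshold = 3, discrimination = 3, identification = 3),
    ...
  )
}

tiny_session <- function(seed = 5, ...) {
  simulate_session("P001", tiny_sim_config(...), montage_config(), seed = seed)
}

# small cached cohort + preprocessed epochs so several test files can reuse it
local_cache <- new.env()

cached_epochs <- function() {
  if (is.null(local_cache$epochs)) {
    s <- tiny_session(seed = 7)
    local_cache$session <- s
    local_cache$epochs <- preprocess_session(s, pipeline_config())
  }
  local_cache$epochs
}

fast_config <- function(...) {
  pipeline_config(
    outer_k = 4, repeats = 1, inner_k = 3, tune = FALSE,
    model = "logistic", bootstrap_reps = 100, seed = 11, ...
  )
}
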