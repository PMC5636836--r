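# shared fixtures: everything is built in code at test time

fixture_profiles <- function(...) prey_profiles(...)

fixture_predators <- function(seed = 1, n = 294) {
  generate_predators(sampling_config(n_predators = n, seed = seed))
}

fixture_stomachs <- function(seed = 1, n_stomachs = 294) {
  generate_stomachs(sampling_config(n_stomachs = n_stomachs, seed = seed),
                    fixture_profiles())
}

# a minimal hand-built stomach table: weights in g, counts of individuals
toy_records <- function() {
  data.frame(
    shark_id = c(1L, 1L, 2L, 3L),
    species = c("gummy_shark", "teleosts", "gummy_shark", "eagle_ray"),
    count = c(2L, 1L, 1L, 1L),
    partly_digested_weight_g = c(1500, 300, 900, 4000))
}
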