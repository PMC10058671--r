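# Shared fixtures: reference models and a seeded random-state generator.

pyr <- pyronaridine_model()
art <- artesunate_model()

# random nonnegative states for property-style derivative checks
random_states <- function(model, n, seed = 101) {
  set.seed(seed)
  tmpl <- state_template(model)
  lapply(seq_len(n), function(i) {
    s <- stats::runif(length(tmpl), 0, 1) * 10^sample(-2:6, length(tmpl), replace = TRUE)
    stats::setNames(s, names(tmpl))
  })
}

total_parent <- function(state) sum(state[c("A_a", "A_blood", "A_lung", "A_trachea", "A_rest")])
total_metab  <- function(state) sum(state[c("A_blood_m", "A_lung_m", "A_trachea_m", "A_rest_m")])
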