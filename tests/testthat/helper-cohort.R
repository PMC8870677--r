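# Shared fixtures: the pooled 8-arm cohort and the three EBRT scenarios.
fixture_arms <- function() ra223_cohort()

fixture_scenarios <- function(params = lq_params()) default_scenarios(params)

# toy grouped dataset used by several outcome-model tests
toy_outcome_data <- function() {
  d <- data.frame(study_id = c("X", "Y", "Z"),
                  eqd2_tot = c(10, 50, 90),
                  events = c(1, 3, 9),
                  n = c(5, 8, 12))
  attr(d, "endpoint") <- "os_2y"
  d
}

# expand grouped (events, n) rows into one Bernoulli row per patient
expand_bernoulli <- function(data) {
  do.call(rbind, lapply(seq_len(nrow(data)), function(i) {
    data.frame(study_id = data$study_id[i],
               eqd2_tot = data$eqd2_tot[i],
               y = rep(c(1, 0), c(data$events[i],
                                  data$n[i] - data$events[i])))
  }))
}
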