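# shared fixtures, all built in code

panmictic_model <- function(size = 1, N_ref = 1) {
  make_custom_model(list(epoch(0, size)), N_ref = N_ref, label = "panmictic")
}

# two islands, immigration ten times stronger in one direction
asymmetric_two_island <- function() {
  make_custom_model(list(
    epoch(0, c(1, 1), matrix(c(0, 1, 0.1, 0), 2, 2, byrow = TRUE))
  ), label = "asymmetric two-island")
}

# two demes exchanging M = 1 merge at T = 2 into one ancestor of size 2,
# keeping the total gene count constant through the split
split_two_island <- function() {
  add_population_split(make_n_island(2, 1), T = 2, ancestral_size = 2)
}

# two completely isolated demes: coalescence impossible across demes
disconnected_model <- function() {
  make_custom_model(list(epoch(0, c(1, 1), matrix(0, 2, 2))))
}

# one-sample Kolmogorov-Smirnov statistic of a t2_sample against the exact
# survival function of its generating model
ks_stat <- function(sample, model, sampling) {
  x <- sort(sample$values)
  n <- length(x)
  Fx <- 1 - survival_and_density(model, sampling, x)$S
  max(pmax(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx)))
}
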