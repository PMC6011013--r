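# Shared in-code fixtures

# three patients, distinct event times, all events
surv3 <- function() {
  survival_data(data.frame(patient_id = c("a", "b", "c"),
                           time = c(1, 2, 3), event = c(1, 1, 1)))
}

# matrix with the single covariate (1, 0, 1) ordered by time
x3 <- function() {
  matrix(c(1, 0, 1), 3, 1, dimnames = list(c("a", "b", "c"), "g1"))
}

two_node_net <- function(w = 1) {
  gene_network(data.frame(from = "A", to = "B", weight = w))
}

# random weighted graph over p genes (weights in (0,1], no self loops)
random_net <- function(p, edge_prob = 0.3) {
  pairs <- t(utils::combn(sprintf("v%02d", seq_len(p)), 2))
  keep <- runif(nrow(pairs)) < edge_prob
  gene_network(data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                          weight = runif(sum(keep), 0.05, 1)))
}

# small planted-signal cohort used across solver tests
small_cohort <- function(seed, n = 60, p = 5, support = c(1, 2),
                         beta_true = c(1, -0.8)) {
  simulate_dataset(sim_config(
    n = n, p = p, n_modules = 1, module_size = p, support = support,
    beta_true = beta_true, rho_within = 0.5, seed = seed))
}

# random censored survival fixture
random_surv <- function(n, event_rate = 0.7) {
  survival_data(data.frame(
    patient_id = sprintf("r%03d", seq_len(n)),
    time = round(rexp(n, 0.1), 3) + 0.01,
    event = rbinom(n, 1, event_rate)))
}
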