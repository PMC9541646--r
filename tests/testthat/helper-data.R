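# small deterministic fixtures built in code

toy_table <- function() {
  community_table(species = c("A", "A", "B", "B"),
                  time = c(1, 2, 1, 2),
                  location = "L1",
                  count = c(3, 5, 0, 2))
}

toy_locations <- function() {
  data.frame(location = c("L1", "L2", "L3"),
             latitude = c(0, 0, 1),
             longitude = c(0, 1, 1),
             habitat = c("forest", "forest", "fragment"))
}

# quick simulated table for fitting tests
small_sim_table <- function(S = 15, Tn = 12, gamma = 0.2, sigma2_e = 0.3,
                            sigma2_h = 0.5, sigma2_c = 0.1, nu = 1,
                            logK = 3, seed = 1) {
  cfg <- simulation_config(n_species = S, n_steps = 320 + Tn, burn_in = 320,
                           gamma = gamma, mu_r = gamma * logK,
                           sigma2_r = gamma^2 * sigma2_h,
                           sigma2_s = 2 * gamma * sigma2_e,
                           sigma2_E = 2 * gamma * sigma2_c,
                           nu = nu, seed = seed)
  as_community_table(simulate_community(cfg))
}

# single-cluster-effect table: species is the cluster, one iid effect
iid_cluster_table <- function(counts, clusters) {
  community_table(species = clusters, time = seq_along(counts),
                  location = "L1", count = counts)
}
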