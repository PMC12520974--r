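# Small synthetic configurations reused across tests.

# Null config: two target subtypes and one query cluster, no attraction.
null_config <- function(n = 1000L, seed = 11L,
                        freqs = c(A = 0.25, B = 0.25, Q = 0.5)) {
  synth_config(
    clusters = list(
      cluster_spec("A", "target", freqs[["A"]], c(0, 0), 1),
      cluster_spec("B", "target", freqs[["B"]], c(20, 0), 1),
      cluster_spec("Q", "query", freqs[["Q"]], c(0, 20), 1)
    ),
    n_ref_cells_per_sample = n,
    n_spatial_cells_per_sample = n,
    samples_per_condition = 1L,
    conditions = c("ctrl", "case"),
    domain_size = 1000,
    seed = seed
  )
}

# Enriched config: query cells attracted to target subtype "A" in "case".
enriched_config <- function(n = 1000L, rho = 0.6, attraction_sd = 15,
                            seed = 12L) {
  synth_config(
    clusters = list(
      cluster_spec("A", "target", 0.10, c(0, 0), 1),
      cluster_spec("B", "target", 0.20, c(20, 0), 1),
      cluster_spec("Q", "query", 0.40, c(0, 20), 1),
      cluster_spec("bg", "other", 0.30, c(20, 20), 1)
    ),
    n_ref_cells_per_sample = n,
    n_spatial_cells_per_sample = n,
    samples_per_condition = 1L,
    conditions = c("ctrl", "case"),
    domain_size = 1000,
    enrichment_target = "A",
    enrichment_rho = c(case = rho),
    attraction_sd = attraction_sd,
    seed = seed
  )
}

# One-sample proximity p-value for a generated spatial sample, via the
# package's own path (nearest_target -> expected_proportions -> binomial).
sample_pvalue <- function(spatial, subtype, target_labels = c("A", "B")) {
  asg <- nearest_target(spatial, "Q", target_labels,
                        label_column = "true_label")
  p0 <- expected_proportions(spatial, target_labels,
                             label_column = "true_label")
  obs <- sum(asg$target_subtype == subtype)
  p0s <- p0$p0[p0$target_subtype == subtype]
  list(observed = obs, n = nrow(asg), p0 = p0s,
       p = binomial_upper_tail(obs, nrow(asg), p0s))
}
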