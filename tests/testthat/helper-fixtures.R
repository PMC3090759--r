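# Shared fixtures: everything is built in code, no stored data files.

rs <- function(start, end) region_set(start, end)

full_hvr <- function() region_set(c(16024, 1), c(16569, 576))

# a small handcrafted dataset with mixed coverage and all token kinds
tiny_dataset <- function() {
  profile_dataset(list(
    sample_profile("S1", rs(c(16024, 73), c(16365, 340)),
      c("16298C", "16311C", "73G"),
      label = "Caucasian", country = "US"
    ),
    sample_profile("S2", rs(c(16024, 73), c(16365, 340)),
      c("16223T", "16124.1C", "263G"),
      label = "African"
    ),
    sample_profile("S3", rs(16024, 16365), c("16189-", "16223T"),
      label = "Asian"
    ),
    sample_profile("S4", rs(c(16024, 1), c(16569, 576)), character(0),
      label = "Caucasian"
    )
  ))
}

# random labelled binary dataset for property tests
random_binary <- function(m, n, seed) {
  set.seed(seed)
  matrix(rbinom(m * n, 1, 0.3), nrow = m)
}

# fast non-tuning pipeline specs used across tests
fast_spec <- function(classifier, k = 5) {
  if (classifier %in% c("nn1", "majority")) {
    pipeline_spec(classifier)
  } else {
    pipeline_spec(classifier, k = k, C = 10, gamma = 0.1)
  }
}

# label accessor without relying on internals
dataset_labels_for_test <- function(d) {
  sort(vapply(d$samples, function(s) s$label, ""))
}

# a separable synthetic world: one haplogroup per class, disjoint motifs,
# no private mutations, full coverage
separable_config <- function(n_samples, seed = 11) {
  synthetic_config(
    n_samples = n_samples,
    class_labels = c("Caucasian", "African", "Asian", "Hispanic"),
    class_proportions = c(0.378, 0.295, 0.172, 0.155),
    n_haplogroups = 4,
    mixing = diag(4),
    motif_size = 6, motif_overlap = 0, private_rate = 0,
    coverage_model = "full", seed = seed
  )
}
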