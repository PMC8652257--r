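# Small builders shared across test files.

# Seeded nested-list prediction-vector tensor (the caps_routing input layout).
random_uhat <- function(N, l, k, m, seed = 1) {
  set.seed(seed)
  lapply(seq_len(l), function(i)
    lapply(seq_len(k), function(j) matrix(rnorm(N * m), N, m)))
}

# A small planted-signal modular config: `l` numeric sources, source i
# informative for class ((i-1) %% k) + 1.
planted_config <- function(n_samples, k, l, len = 5, delta = 2, sigma = 1,
                           seed = 1) {
  sources <- lapply(seq_len(l), function(i)
    synth_source("numeric", len, informative_for = ((i - 1) %% k) + 1))
  synth_config(n_samples, k, sources, delta = delta, sigma = sigma,
               seed = seed)
}

# Tiny trained-in-seconds fixture for smoke tests. The raised learning rate
# compensates for the few Adam steps a 300-sample run provides.
tiny_fit <- function(seed = 1, epochs = 8, n_samples = 300, k = 2, l = 2) {
  gen <- generate_modular(planted_config(n_samples, k, l, seed = seed))
  fit <- train_caps(gen$dataset,
                    train_config(epochs = epochs, seed = seed,
                                 repeats = 1, batch_size = 64,
                                 learning_rate = 5e-3),
                    n = 4, m = 6)
  list(gen = gen, fit = fit)
}

# Synthetic regulon-style collection: n_sets sets labeled by gene symbols,
# a known subset containing their own label.
synthetic_regulons <- function(n_sets = 253, n_with_label = 40,
                               genes_per_set = 6, seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%04d", 1:2000)
  labels <- sample(genes, n_sets)
  with_label <- sample.int(n_sets, n_with_label)
  sets <- lapply(seq_len(n_sets), function(s) {
    members <- sample(setdiff(genes, labels[s]), genes_per_set)
    if (s %in% with_label) members <- c(members, labels[s])
    list(label = labels[s], category = "regulon", genes = members)
  })
  gene_set_collection(sets)
}
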