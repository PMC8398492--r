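# Small cohort and image fixtures shared across test files. Everything is
# generated in code; no stored data.

# compact 4-group cohort with a strong planted power effect at node 3
small_spec <- function(n_per_group = 6, n_nodes = 8, n_timepoints = 96,
                       planted_node = 3, rng_seed = 7,
                       power = c(ASD = 2.5, APD = 1.8, `PDD-NOS` = 1.4, NC = 1),
                       coupling = c(ASD = 0.9, APD = 0.6, `PDD-NOS` = 0.3, NC = 0.05)) {
  cohort_spec(n_per_group = n_per_group, n_nodes = n_nodes,
              n_timepoints = n_timepoints, planted_node = planted_node,
              power_effects = power, coupling_effects = coupling,
              rng_seed = rng_seed)
}

# effect-free spec: all groups exchangeable at every node
null_spec <- function(rng_seed, n_per_group = 8, n_nodes = 4,
                      n_timepoints = 96) {
  cohort_spec(n_per_group = n_per_group, n_nodes = n_nodes,
              n_timepoints = n_timepoints, planted_node = 2,
              power_effects = c(ASD = 1, APD = 1, `PDD-NOS` = 1, NC = 1),
              coupling_effects = c(ASD = .5, APD = .5, `PDD-NOS` = .5, NC = .5),
              rng_seed = rng_seed)
}

# strongly separable two-class toy images (block in a class-dependent corner)
toy_images <- function(n_per_class, size = 16, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- array(runif(size * size * 3 * n) * 0.2, dim = c(size, size, 3, n))
  a <- seq_len(n_per_class)
  lo <- 3:(size %/% 2); hi <- (size %/% 2 + 2):(size - 2)
  x[lo, lo, , a] <- x[lo, lo, , a] + 0.7
  x[hi, hi, , n_per_class + a] <- x[hi, hi, , n_per_class + a] + 0.7
  list(x = x, y = rep(c("A", "B"), each = n_per_class))
}

# one quick roi_ts with given node count
toy_recording <- function(n_nodes = 6, n_timepoints = 96, seed = 1,
                          group = "ASD", site = "S1") {
  set.seed(seed)
  roi_time_series("subj1", site, group,
                  matrix(rnorm(n_timepoints * n_nodes), n_timepoints, n_nodes),
                  tr_seconds = 2)
}

# brute-force one-way ANOVA permutation p-value (oracle; independent of the
# implementation under test)
perm_anova_p <- function(groups, n_perm = 4000, seed = 99) {
  y <- unlist(groups)
  sizes <- vapply(groups, length, integer(1))
  g <- rep(seq_along(groups), sizes)
  fstat <- function(y, g) {
    gm <- mean(y)
    means <- tapply(y, g, mean)
    ssb <- sum(sizes * (means - gm)^2)
    ssw <- sum((y - means[g])^2)
    (ssb / (length(sizes) - 1)) / (ssw / (length(y) - length(sizes)))
  }
  f0 <- fstat(y, g)
  set.seed(seed)
  hits <- 0
  for (i in seq_len(n_perm)) {
    if (fstat(sample(y), g) >= f0 - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}
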