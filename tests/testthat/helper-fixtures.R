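# shared fixtures: tiny in-code tables and quiet wrappers

# a complete, well-formed table covering all four species
tiny_table <- function(n_per = 4, seed = 101) {
  cfg <- otter_sim_config(missing_rate = 0, bilateral_sd = 0)
  cfg$groups <- lapply(cfg$groups, function(g) { g$n <- n_per; g })
  simulate_otters(cfg, seed = seed)$table
}

# default-condition simulated study table (151 specimens, ~1% missing)
study_table <- function(seed = 7) simulate_otters(otter_sim_config(), seed = seed)$table

# deterministic toy matrix with named trait columns
toy_log_matrix <- function(n = 6, traits = c("A", "B", "C"), seed = 3) {
  set.seed(seed)
  m <- matrix(rnorm(n * length(traits), 2, 0.3), n,
              dimnames = list(NULL, traits))
  m
}

# brute-force SSCP MANOVA oracle for a one-way layout (no nesting):
# computes Wilks' lambda from group-mean/grand-mean cross products directly
oracle_wilks_oneway <- function(Y, g) {
  g <- factor(g)
  gm <- colMeans(Y)
  H <- matrix(0, ncol(Y), ncol(Y))
  E <- matrix(0, ncol(Y), ncol(Y))
  for (lev in levels(g)) {
    Yi <- Y[g == lev, , drop = FALSE]
    mi <- colMeans(Yi)
    H <- H + nrow(Yi) * tcrossprod(mi - gm)
    E <- E + crossprod(sweep(Yi, 2, mi))
  }
  list(lambda = det(E) / det(E + H), E = E, H = H)
}
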