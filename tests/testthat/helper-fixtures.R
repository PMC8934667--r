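# Small fixtures built in code.

# scaled-down circular study genome: 1 Mb, terminus 280-400 kb, dif at
# 340 kb, oriC at 840 kb (same topology as the full-size system)
toy_sim_genome <- function(length = 1e6) {
  genome("toy", length = length, circular = TRUE,
         anchors = c(dif = 0.34 * length, oriC = 0.84 * length),
         spans = list(terminus = c(0.28, 0.40) * length))
}

toy_sim_params <- function(bin_size = 5000, ...) {
  sim_params(genome = toy_sim_genome(), bin_size = bin_size,
             total_pairs = 2e5, precat_range = c(2.5e4, 1e5),
             wing_width = 5e4, wing_guard = 1e5, ...)
}

# symmetric random contact map with an optional mask
random_map <- function(n = 20, bin_size = 10, seed = 1, mask = NULL,
                       state = "raw") {
  set.seed(seed)
  M <- matrix(stats::rpois(n * n, 30) + 1, n, n)
  M <- M + t(M)
  g <- genome(paste0("rnd", seed), length = n * bin_size)
  m <- rep(FALSE, n)
  if (!is.null(mask)) m[mask] <- TRUE
  contact_map(g, bin_size, M, mask = m, state = state)
}

# contact map from an explicit matrix, state "normalized" (for comparison
# operations that require normalized inputs)
as_norm_map <- function(values, bin_size = 1000, genome_obj = NULL) {
  n <- nrow(values)
  g <- genome_obj %||% genome("m", length = n * bin_size)
  contact_map(g, bin_size, values, state = "normalized")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# circular power-law decay matrix on n bins
decay_matrix <- function(n, bin_size = 1000, gamma = 1, s0 = 1000) {
  d <- 0:(n - 1)
  d <- pmin(d, n - d) * bin_size
  stats::toeplitz((s0 + d)^(-gamma))
}

# circular separation matrix in bp
separation_matrix <- function(n, bin_size = 1000) {
  d <- 0:(n - 1)
  d <- pmin(d, n - d) * bin_size
  stats::toeplitz(d)
}
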