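## Shared small fixtures, built once per test run.

two_chrom_config <- function(n_lines = 80L, markers = 15L, seed = 101L,
                             n_envs = 4L, qtl_specs = list(), ...) {
  chrs <- data.frame(chrom = c("1", "2"), length_morgan = c(1, 0.8),
                     length_bp = c(9e7, 7e7))
  sim_config(n_lines = n_lines, chromosomes = chrs,
             markers_per_chromosome = markers,
             env_specs = default_environments()[seq_len(n_envs), ],
             qtl_specs = qtl_specs, seed = seed, ...)
}

## one moderate simulated dataset reused across read-only tests
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_magic_met(
        two_chrom_config(n_lines = 120L, markers = 15L, seed = 2024L,
                         sigma2_L = 1, sigma2_LxE = 0.4,
                         prob_softening = 0.02))
    cache
  }
})

## deterministic cell-means builder for regression-style tests
toy_cells <- function(n_lines, n_envs, seed = 1L, noise = 0) {
  if (!is.null(seed)) set.seed(seed)
  cells <- outer(rnorm(n_lines, 10, 2), rnorm(n_envs, 0, 2), "+") +
    matrix(rnorm(n_lines * n_envs, 0, noise), n_lines)
  dimnames(cells) <- list(sprintf("L%03d", seq_len(n_lines)),
                          sprintf("E%02d", seq_len(n_envs)))
  cells
}
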