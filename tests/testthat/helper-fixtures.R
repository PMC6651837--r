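# Shared fixtures: all data is generated in code, nothing is read from disk.

# a small hyper-parameter lattice that keeps unit tests fast while still
# exercising both modes and several orders of magnitude
tiny_grid <- function() {
  svr_grid(cost = c(1, 16, 256), gamma = c(2^-5, 2^-1),
           epsilon = 0.1, nu = 0.5)
}

# descriptor table with an exactly linear response in one informative column
# plus independent noise columns
linear_in_A <- function(n = 40, p_noise = 3, noise_sd = 0, seed = 1) {
  set.seed(seed)
  d <- tibble::tibble(id = sprintf("c%03d", seq_len(n)),
                      A = rnorm(n))
  for (j in seq_len(p_noise)) d[[paste0("noise", j)]] <- rnorm(n)
  d$logPe <- -6 + 0.8 * d$A + rnorm(n, sd = noise_sd)
  d
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
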