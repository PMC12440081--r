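# random valid decompositions: coefficients representative of measured games
# (interaction strengths within (-1, 1), selection within (0, 0.5) in
# magnitude), respecting payoff positivity
random_decomposition <- function(n = 1, s_range = c(0.02, 0.5),
                                 alpha_max = 0.8, allow_negative_s = TRUE) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      s <- runif(1, s_range[1], s_range[2]) *
        (if (allow_negative_s) sample(c(-1, 1), 1) else 1)
      awm <- runif(1, -alpha_max, alpha_max)
      amw <- runif(1, -alpha_max, alpha_max)
      if (1 + s > 0.05 && 1 + s + amw > 0.05 && 1 + awm > 0.05) break
    }
    out[[i]] <- game_decomposition(s, awm, amw)
  }
  if (n == 1) out[[1]] else out
}

x_grid_101 <- seq(0, 1, length.out = 101)
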