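# Shared fixtures, all generated in code.

vis_grid <- function(step = 1) seq(400, 700, by = step)

# Random lossless/lossy stack for property tests (seeded by the caller).
random_stack <- function(n_layers, lossy = FALSE) {
  layers <- lapply(seq_len(n_layers), function(i) {
    n <- runif(1, 1, 2)
    k <- if (lossy) runif(1, 0, 0.05) else 0
    layer(optical_material(sprintf("m%d", i), n, k),
          runif(1, 40, 400))
  })
  optical_stack(layers)
}

# Independent closed-form oracle for the paired t statistic.
t_oracle <- function(d) {
  tt <- mean(d) / (sd(d) / sqrt(length(d)))
  list(t = tt, df = length(d) - 1L, p = 2 * pt(-abs(tt), length(d) - 1L))
}
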