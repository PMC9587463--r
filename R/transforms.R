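# Unconstrained parameterisation of the curve parameters, used both when
# sampling family deviations in the generator and as the MCMC sampling scale:
#   z = (L, log(U - L), log(a - 1), log(b - 1), log h)
# Working with log(a - 1) and log(b - 1) keeps a > 1 and b > 1 for every
# real-valued z, which guarantees a*b > 1 and hence an interior optimum.

tpc_z_names <- c("ctmin", "log_span", "log_shape_a", "log_shape_b",
                 "log_height")

tpc_to_z <- function(lower, upper, shape_a, shape_b, height) {
  c(lower, log(upper - lower), log(shape_a - 1), log(shape_b - 1),
    log(height))
}

tpc_from_z <- function(z) {
  list(lower = z[[1L]], upper = z[[1L]] + exp(z[[2L]]),
       shape_a = 1 + exp(z[[3L]]), shape_b = 1 + exp(z[[4L]]),
       height = exp(z[[5L]]))
}
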