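# Shared fixtures, built in code at test time (no stored data).

fixture_blood <- function(dt = 0.02) {
  analytic_input_function(grid = seq(0, 65, by = dt))
}

fixture_schedule <- function() default_schedule()

# 22-frame input sub-schedule of the default protocol
fixture_input_schedule <- function(sch = default_schedule()) {
  frame_schedule(sch$starts[1:22], sch$ends[1:22], sch$decay_lambda)
}

# small, fast phantom for network/training tests (shape divisible by 16)
fixture_small_phantom <- function(seed = 1, shape = c(32, 32),
                                  noise_scale = 2.0) {
  generate_phantom(sample_phantom_spec(seed, shape = shape,
                                       noise_scale = noise_scale),
                   default_schedule(), fixture_blood(0.05), dt = 0.1)
}

# build (input, truth, ...) training sample from a generated phantom
fixture_sample <- function(ph) {
  sch <- ph$schedule
  suv <- to_suv(ph$noisy)
  input <- dynamic_series(suv$frames[1:22, , , drop = FALSE],
                          fixture_input_schedule(sch))
  list(input = input, truth = suv, blood = ph$blood, schedule = sch,
       ki_true = ph$ki_true, clean_suv = to_suv(ph$clean), noisy_suv = suv)
}

# random non-degenerate kinetic parameters within physiological ranges
fixture_random_params <- function(k4_zero = FALSE) {
  kinetic_params(f_v = runif(1, 0, 0.3), K1 = runif(1, 0.05, 1.2),
                 k2 = runif(1, 0.05, 1.2), k3 = runif(1, 0.01, 0.4),
                 k4 = if (k4_zero) 0 else runif(1, 0, 0.15))
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / max(sum(b^2), 1e-300))
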