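# shared fixtures, built in code

# minimal valid groups table around given decay parameters
make_groups <- function(theta_a = 0.8, theta_b = 25, theta_c = -0.5,
                        species = "Sp1", site = "X1") {
  g <- expand.grid(species = species, site = site, stringsAsFactors = FALSE)
  g$theta_a <- theta_a; g$theta_b <- theta_b; g$theta_c <- theta_c
  n <- nrow(g)
  g$true_t50 <- if (n > 1) seq(42, 46, length.out = n) else 44
  g$tleafmax_target <- g$true_t50 - 5
  g$leaf_xi <- 30; g$leaf_omega <- 2.5; g$leaf_alpha <- 4
  g$growth_temperature <- 20; g$max_air_temperature <- 30
  g
}

# a small but fully valid study config; override any study_config() argument
tiny_config <- function(groups = make_groups(), seed = 42, ...) {
  study_config(groups = groups, seed = seed, ...)
}

# back-solve theta_b so the curve crosses (1 - fraction) * ref at t_target
theta_b_for <- function(t_target, theta_a, theta_c, ref = 0.803,
                        fraction = 0.5) {
  -log(1 - (1 - fraction) * ref / theta_a) - theta_c * t_target
}

# noiseless treated-only observation table from known parameters
noiseless_obs <- function(theta_a = 0.8, theta_b = 25, theta_c = -0.5,
                          targets = c(34, 38, 42, 44, 46, 48, 50),
                          leaves = 6) {
  temp <- rep(targets, each = leaves) +
    seq(-0.5, 0.5, length.out = leaves * length(targets))
  data.frame(species = "Sp1", site = "X1",
             leaf_id = sprintf("L%03d", seq_along(temp)),
             temperature = temp,
             fvfm = pmax(0, eq1_predict(theta_a, theta_b, theta_c, temp)),
             control_fvfm = NA_real_)
}

# random admissible declining curve with thresholds inside a sane domain
random_admissible_curve <- function() {
  theta_a <- runif(1, 0.5, 0.9)
  theta_c <- -runif(1, 0.05, 2)
  t_zero <- runif(1, 40, 55)           # where the curve hits zero
  theta_b <- -theta_c * t_zero
  t_high <- t_zero + 2
  # domain wide enough that Tcrit (at most ln(0.15)/0.05 = 38 C below the
  # upper edge) always falls inside it
  response_curve(theta_a, theta_b, theta_c, t_low = t_high - 80,
                 t_high = t_high,
                 reference_fvfm = runif(1, 0.4, 1) * theta_a)
}

# numeric root-finding oracles, independent of the closed forms
numeric_tcrit <- function(curve, slope_fraction = 0.15) {
  target <- slope_fraction *
    eq1_slope_magnitude(curve$theta_a, curve$theta_b, curve$theta_c,
                        curve$t_high)
  uniroot(function(tt) eq1_slope_magnitude(curve$theta_a, curve$theta_b,
                                           curve$theta_c, tt) - target,
          lower = curve$t_high - 1000, upper = curve$t_high,
          tol = 1e-12)$root
}

numeric_reduction_threshold <- function(curve, fraction,
                                        reference = curve$reference_fvfm) {
  target <- (1 - fraction) * reference
  t_zero <- -curve$theta_b / curve$theta_c  # y = 0 here, below target
  uniroot(function(tt) eq1_predict(curve$theta_a, curve$theta_b,
                                   curve$theta_c, tt) - target,
          lower = t_zero - 2000, upper = t_zero, tol = 1e-12)$root
}
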