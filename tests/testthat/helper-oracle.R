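# Independent brute-force oracle for the segment thermodynamics: explicit
# scalar loops, plain half-step damped iteration, no shared code with the
# package implementation beyond the model definition itself.

oracle_R <- 1.9872042586e-3

oracle_pair_energy <- function(s1, s2, params) {
  lo <- min(s1, s2); hi <- max(s1, s2)
  params$alpha_prime / 2 * (s1 + s2)^2 +
    params$c_hb * min(0, lo + params$sigma_hb) * max(0, hi - params$sigma_hb)
}

oracle_mu <- function(grid, p, T, params, tol = 1e-12, iters = 50000) {
  RT <- oracle_R * T
  n <- length(grid)
  mu <- rep(0, n)
  for (it in seq_len(iters)) {
    mu_new <- numeric(n)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(n)) {
        E <- oracle_pair_energy(grid[i], grid[j], params)
        s <- s + p[j] * exp((mu[j] - E) / RT)
      }
      mu_new[i] <- -RT * log(s)
    }
    if (max(abs(mu_new - mu)) < tol) return(mu_new)
    mu <- (mu + mu_new) / 2
  }
  stop("oracle iteration did not converge")
}

# ensemble weights of a mixture by explicit loops
oracle_ensemble <- function(comps, x) {
  n <- length(comps[[1]]$profile$grid)
  w <- numeric(n)
  area <- 0
  for (k in seq_along(comps)) {
    for (i in seq_len(n)) w[i] <- w[i] + x[k] * comps[[k]]$profile$areas[i]
    area <- area + x[k] * sum(comps[[k]]$profile$areas)
  }
  list(p = w / area, area = area)
}

oracle_sg <- function(comp, comps, x, params) {
  r <- function(cc) cc$profile$cavity_volume / params$comb_r0
  q <- function(cc) cc$profile$cavity_area / params$comb_q0
  sr <- 0; sq <- 0; sl <- 0
  z <- params$comb_z
  l <- function(cc) (z / 2) * (r(cc) - q(cc)) - (r(cc) - 1)
  for (k in seq_along(comps)) {
    sr <- sr + x[k] * r(comps[[k]])
    sq <- sq + x[k] * q(comps[[k]])
    sl <- sl + x[k] * l(comps[[k]])
  }
  pbx <- r(comp) / sr
  tbp <- (q(comp) / sq) / pbx
  log(pbx) + (z / 2) * q(comp) * log(tbp) + l(comp) - pbx * sl
}

oracle_mu_compound <- function(comp, comps, x, T, params) {
  ens <- oracle_ensemble(comps, x)
  mu <- oracle_mu(comp$profile$grid, ens$p, T, params)
  s <- 0
  for (i in seq_along(mu)) s <- s + comp$profile$areas[i] * mu[i]
  s / params$a_eff + oracle_R * T * oracle_sg(comp, comps, x, params)
}

oracle_lngamma <- function(comp, comps, x, T, params) {
  (oracle_mu_compound(comp, comps, x, T, params) -
     oracle_mu_compound(comp, list(comp), 1, T, params)) / (oracle_R * T)
}

oracle_enthalpy <- function(comp, comps, x, T, params) {
  dT <- params$dT
  m1 <- oracle_mu_compound(comp, comps, x, T - dT, params)
  m2 <- oracle_mu_compound(comp, comps, x, T + dT, params)
  (m2 / (T + dT) - m1 / (T - dT)) / (1 / (T + dT) - 1 / (T - dT))
}

oracle_hex <- function(a, b, x, T, params) {
  comps <- list(a, b)
  h <- 0
  for (k in 1:2) {
    if (x[k] == 0) next
    h <- h + x[k] * (oracle_enthalpy(comps[[k]], comps, x, T, params) -
                       oracle_enthalpy(comps[[k]], list(comps[[k]]), 1, T,
                                       params))
  }
  h
}
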