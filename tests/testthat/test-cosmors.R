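params <- cosmo_parameters()

test_that("pair interaction energies follow the misfit + hydrogen-bond form", {
  # perfectly matched screening charges, no hydrogen bond
  expect_identical(pair_interaction_energy(0, 0, params), 0)
  # opposite charges below the hb threshold: misfit vanishes, hb inactive
  s <- params$sigma_hb * 0.9
  expect_equal(pair_interaction_energy(s, -s, params), 0, tolerance = 1e-15)
  # direct scalar substitution for a strong donor/acceptor contact
  e <- pair_interaction_energy(0.02, -0.02, params)
  hand <- params$c_hb * (-0.02 + params$sigma_hb) * (0.02 - params$sigma_hb)
  expect_equal(e, hand, tolerance = 1e-12)
  expect_lt(e, 0)
  # symmetry in the arguments
  s1 <- seq(-0.02, 0.02, by = 0.005)
  expect_equal(outer(s1, s1, pair_interaction_energy, params = params),
               t(outer(s1, s1, pair_interaction_energy, params = params)))
})

test_that("the sigma-potential solver finds and keeps the fixed point", {
  # all surface at sigma = 0: E(0,0) = 0 forces mu = 0 there
  g <- c(-0.001, 0, 0.001)
  cc <- toy_compound("neutralspike", g, c(0, 50, 0))
  pot <- solve_sigma_potential(pure_mixture(cc), params)
  expect_true(pot$converged)
  expect_equal(pot$mu[2], 0, tolerance = 1e-8)

  # refeeding a converged solution returns it unchanged (fixed point)
  da <- toy_donor_acceptor_pair()
  mix <- mixture(list(da$donor, da$acceptor), c(0.5, 0.5))
  pot1 <- solve_sigma_potential(mix, params)
  pot2 <- solve_sigma_potential(mix, params, init = pot1$mu)
  expect_equal(pot2$mu, pot1$mu, tolerance = 1e-7)

  # convergence is initialization-independent on realistic ensembles:
  # random and zero starts agree within 10x the solver tolerance
  drugs <- fixture_drugs()
  lib <- generate_candidate_library(n = 6, seed = 2)$candidates
  cand <- candidate_compound(lib[lib$hb_character == "complement_strong",
                                 ][1, ])
  rmix <- mixture(list(drugs$drug_basic_A, cand), c(0.5, 0.5))
  r1 <- solve_sigma_potential(rmix, params)
  set.seed(7)
  r2 <- solve_sigma_potential(rmix, params, init = rnorm(51))
  expect_lt(max(abs(r1$mu - r2$mu)), 10 * params$tol)

  # degenerate all-zero ensembles are impossible to construct upstream
  expect_error(toy_compound("zero", g, c(0, 0, 0)), "zero total area")
})

test_that("engine matches the brute-force oracle on small-grid systems", {
  g3 <- c(-0.015, 0, 0.015)
  a3 <- toy_compound("a3", g3, c(20, 60, 5), volume = 90)
  b3 <- toy_compound("b3", g3, c(2, 55, 25), volume = 120)
  g4 <- c(-0.02, -0.005, 0.01, 0.025)
  a4 <- toy_compound("a4", g4, c(12, 40, 30, 3), volume = 105)
  b4 <- toy_compound("b4", g4, c(0, 30, 30, 15), volume = 95)

  for (pair in list(list(a3, b3), list(a4, b4))) {
    a <- pair[[1]]; b <- pair[[2]]
    mix <- mixture(list(a, b), c(0.5, 0.5))
    pot <- solve_sigma_potential(mix, params)
    ens <- oracle_ensemble(list(a, b), c(0.5, 0.5))
    expect_equal(pot$mu, oracle_mu(a$profile$grid, ens$p, 298.15, params),
                 tolerance = 1e-8)
    expect_equal(pseudochemical_potential(a, mix, params),
                 oracle_mu_compound(a, list(a, b), c(0.5, 0.5), 298.15,
                                    params),
                 tolerance = 1e-8)
    expect_equal(log(activity_coefficient(a, mix, params)),
                 oracle_lngamma(a, list(a, b), c(0.5, 0.5), 298.15, params),
                 tolerance = 1e-8)
    expect_equal(excess_enthalpy(a, b, c(0.5, 0.5), 298.15, params),
                 oracle_hex(a, b, c(0.5, 0.5), 298.15, params),
                 tolerance = 1e-8)
  }
})

test_that("activity coefficients honour the pure-liquid reference state", {
  da <- toy_donor_acceptor_pair()
  # pure compound: gamma = 1 exactly
  for (cc in da) {
    expect_equal(activity_coefficient(cc, pure_mixture(cc), params), 1,
                 tolerance = 1e-9)
  }
  # 1:1 mixture of two copies of the same compound: indistinguishable
  twin <- mixture(list(da$donor, da$donor), c(0.5, 0.5))
  expect_equal(activity_coefficient(da$donor, twin, params), 1,
               tolerance = 1e-9)
  # asymmetric mixtures deviate from ideality
  mix <- mixture(list(da$donor, da$acceptor), c(0.5, 0.5))
  expect_lt(activity_coefficient(da$donor, mix, params), 1)
})

test_that("excess enthalpy obeys its reference-state identities", {
  da <- toy_donor_acceptor_pair()
  drugs <- fixture_drugs()
  # self-mixing and the pure limit give zero
  expect_equal(excess_enthalpy(da$donor, da$donor, params = params), 0,
               tolerance = 1e-9)
  expect_equal(excess_enthalpy(da$donor, da$acceptor, c(1, 0),
                               params = params), 0, tolerance = 1e-9)
  # symmetry under swapping the components at 1:1
  h1 <- excess_enthalpy(da$donor, da$acceptor, params = params)
  h2 <- excess_enthalpy(da$acceptor, da$donor, params = params)
  expect_equal(h1, h2, tolerance = 1e-9)
  lib <- generate_candidate_library(n = 4, seed = 1)$candidates
  cand <- candidate_compound(lib[1, ])
  hA <- excess_enthalpy(drugs$drug_basic_A, cand, params = params)
  hA2 <- excess_enthalpy(cand, drugs$drug_basic_A, params = params)
  expect_equal(hA, hA2, tolerance = 1e-9)
  # hydrogen-bond pairing lowers the enthalpy: donor + acceptor mix
  expect_lt(h1, 0)
})

test_that("the Gibbs-Helmholtz finite difference is step-size consistent", {
  da <- toy_donor_acceptor_pair()
  mix <- mixture(list(da$donor, da$acceptor), c(0.5, 0.5))
  h5 <- partial_enthalpy(da$donor, mix, params = params, dT = 5)
  h25 <- partial_enthalpy(da$donor, mix, params = params, dT = 2.5)
  # central differences are O(dT^2): halving the step must agree closely
  expect_equal(h5, h25, tolerance = 1e-3)

  # a flat (temperature-independent mu/T) system has zero enthalpy:
  # all surface at sigma = 0 gives mu = 0 at every temperature
  g <- c(-0.001, 0, 0.001)
  cc <- toy_compound("flat", g, c(0, 50, 0))
  expect_equal(partial_enthalpy(cc, pure_mixture(cc), params = params), 0,
               tolerance = 1e-7)
})

test_that("parameter files round-trip with provenance", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_cosmo_parameters(params, f)
  p2 <- read_cosmo_parameters(f)
  expect_equal(p2$alpha_prime, params$alpha_prime)
  expect_equal(p2$sigma_hb, params$sigma_hb)
  expect_equal(p2$a_eff, params$a_eff)
  expect_match(parameter_checksum(f), "^[0-9a-f]{32}$")
})
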