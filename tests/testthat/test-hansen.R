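solv <- reference_solvents()

test_that("the bundled reference solvent table is well-formed", {
  expect_equal(nrow(solv), 29L)
  expect_true(all(c("delta_d", "delta_p", "delta_h",
                    "molar_volume_cm3mol") %in% names(solv)))
  # the set spans dispersive, polar and hydrogen-bonding space
  expect_gt(stats::sd(solv$delta_p), 3)
  expect_gt(stats::sd(solv$delta_h), 5)
})

test_that("the regular-solution ln gamma behaves as a squared distance", {
  s <- hansen_parameters(17, 8, 10)
  # identical parameters: ln gamma = 0
  expect_equal(hansen_lngamma(s, s, V_x = 100), 0)
  # linear in the molar volume
  other <- hansen_parameters(15, 4, 6)
  expect_equal(hansen_lngamma(s, other, V_x = 200),
               2 * hansen_lngamma(s, other, V_x = 100), tolerance = 1e-12)
  # unit-consistent hand evaluation: V = 100 cm^3/mol, T = 298.15 K,
  # delta differences (2, 3, 0) MPa^0.5, alpha = 4:
  # ln gamma = 100 * (4*4 + 9 + 0) J/mol / (8.314462618 * 298.15) J/mol
  a <- hansen_parameters(17, 8, 10)
  b <- hansen_parameters(15, 5, 10)
  hand <- 100 * (4 * 2^2 + 3^2) / (8.314462618 * 298.15)
  expect_equal(hansen_lngamma(a, b, V_x = 100), hand, tolerance = 1e-12)
  expect_gte(hansen_lngamma(a, b, V_x = 100), 0)
  # the MPa -> J/cm^3 conversion is the identity, centralized and tested
  expect_identical(mpa_to_J_cm3(13), 13)
})

test_that("the sigmoid transform separates good from bad solvents", {
  cfg <- sigmoid_config()
  expect_equal(sigmoid_f(cfg$center, cfg), 0.5)
  expect_equal(sigmoid_f(-1e6, cfg), 1)
  expect_equal(sigmoid_f(1e6, cfg), 0)
  lg <- seq(-5, 10, by = 0.5)
  expect_true(all(diff(sigmoid_f(lg, cfg)) < 0))
})

test_that("noise-free self-consistent targets are recovered almost exactly", {
  truth <- hansen_parameters(17, 8, 10)
  lg <- vapply(seq_len(nrow(solv)), function(i)
    hansen_lngamma(truth, solv[i, ], V_x = 150), numeric(1))
  fit <- fit_hansen(lg, solv, V_x = 150)
  expect_lt(max(abs(coef(fit)[1:3] - c(17, 8, 10))), 0.1)
  # total follows Pythagoras
  expect_equal(coef(fit)[["delta_total"]],
               sqrt(sum(coef(fit)[1:3]^2)), tolerance = 1e-9)
  expect_equal(hansen_parameters(3, 4, 0)$delta_total, 5)
  # optimum is at least as good as every multi-start initial point
  expect_true(all(fit$objective <= fit$start_objectives + 1e-12))
  # the fit is invariant to solvent ordering
  perm <- sample(seq_len(nrow(solv)))
  fit_perm <- fit_hansen(lg[perm], solv[perm, ], V_x = 150)
  expect_equal(coef(fit_perm), coef(fit), tolerance = 1e-4)
})

test_that("recovery degrades gracefully under target noise", {
  cfg <- sigmoid_config()
  truth <- hansen_parameters(17, 8, 10)
  lg <- vapply(seq_len(nrow(solv)), function(i)
    hansen_lngamma(truth, solv[i, ], V_x = 150), numeric(1))
  set.seed(101)
  f_noisy <- pmin(pmax(sigmoid_f(lg, cfg) + stats::rnorm(length(lg), 0, 0.05),
                       1e-6), 1 - 1e-6)
  # invert the sigmoid to express the noisy targets on the ln gamma scale
  lg_noisy <- cfg$center - log(f_noisy / (1 - f_noisy)) / cfg$steepness
  fit <- fit_hansen(lg_noisy, solv, V_x = 150)
  expect_lt(max(abs(coef(fit)[1:3] - c(17, 8, 10))), 1)
})

test_that("parameter recovery holds across a population of solutes", {
  set.seed(11)
  errs <- replicate(20, {
    tr <- c(stats::runif(1, 14, 20), stats::runif(1, 2, 14),
            stats::runif(1, 2, 18))
    V <- stats::runif(1, 80, 220)
    truth <- hansen_parameters(tr[1], tr[2], tr[3])
    lg <- vapply(seq_len(nrow(solv)), function(i)
      hansen_lngamma(truth, solv[i, ], V_x = V), numeric(1))
    fit <- fit_hansen(lg, solv, V_x = V)
    abs(coef(fit)[1:3] - tr)
  })
  expect_lt(stats::median(errs), 0.5)
})

test_that("degenerate solvent sets are rejected", {
  one <- solv[rep(1, 8), ]
  expect_error(fit_hansen(rep(1, 8), one, V_x = 100), "ill-posed")
  expect_error(fit_hansen(rep(1, 3), solv[1:3, ], V_x = 100), "at least 4")
})

test_that("hansen_fit methods are coherent", {
  truth <- hansen_parameters(18, 6, 12)
  lg <- vapply(seq_len(nrow(solv)), function(i)
    hansen_lngamma(truth, solv[i, ], V_x = 120), numeric(1))
  fit <- fit_hansen(lg, solv, V_x = 120)
  expect_named(coef(fit), c("delta_d", "delta_p", "delta_h", "delta_total"))
  expect_length(predict(fit), nrow(solv))
  expect_equal(predict(fit, type = "f"), fitted(fit), tolerance = 1e-12)
  expect_equal(residuals(fit), fit$f_target - fitted(fit))
  expect_output(print(summary(fit)), "Hansen")
  f <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("the engine route estimates totals in a plausible range", {
  # a small synthetic solvent panel with profiles: polar donor/acceptor
  # character loosely tracking the tabulated hydrogen-bonding parameter
  sub <- solv[c(2, 3, 7, 11, 15, 17, 18, 22, 27), ]
  mkprof <- function(dh, dp) {
    don <- min(0.25, dh / 80)
    acc <- min(0.25, (dh + dp) / 120)
    generate_profile(profile_spec(
      data.frame(center = c(0, -0.014, 0.014),
                 width = c(0.004, 0.002, 0.002),
                 share = c(1 - don - acc, don, acc)),
      total_area = 150, total_volume = 180))
  }
  solvc <- lapply(seq_len(nrow(sub)), function(i)
    compound(sub$name[i], mkprof(sub$delta_h[i], sub$delta_p[i]),
             molar_volume = sub$molar_volume_cm3mol[i],
             state_flag = "liquid", molecular_weight = 80))
  drug <- fixture_drugs()$drug_basic_A
  fit <- fit_hansen_engine(drug, solvc, sub)
  expect_s3_class(fit, "hansen_fit")
  expect_gt(coef(fit)[["delta_total"]], 10)
  expect_lt(coef(fit)[["delta_total"]], 40)
})
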