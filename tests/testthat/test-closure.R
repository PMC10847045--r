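test_that("porter allocation is symmetric, annihilating and conservative", {
  # uniform frequencies over two classes, one substrate each
  out <- allocate_porters(0.01, c(sugar = 0.5, amino_acid = 0.5),
                          c("sugar", "amino_acid"))
  expect_equal(out, c(0.005, 0.005))
  # zero frequency annihilates the class
  out2 <- allocate_porters(0.01, c(sugar = 1, organic_acid = 0),
                           c("organic_acid", "organic_acid", "sugar"))
  expect_equal(out2[1:2], c(0, 0))
  expect_equal(sum(out2), 0.01)
  # conservation on a random 82-substrate table
  set.seed(3)
  classes <- sample(c("sugar", "organic_acid", "amino_acid", "fatty_acid",
                      "nucleotide", "auxin"), 82, replace = TRUE)
  z <- stats::runif(6); names(z) <- unique(classes)[1:6]
  z <- z / sum(z)
  out3 <- allocate_porters(0.037, z, classes)
  expect_equal(sum(out3), 0.037, tolerance = 1e-12)
})

test_that("zero class frequency propagates to zero uptake capacity", {
  iso <- fixture_isolates(2, seed = 5)
  zc <- grep("^z_rho_", names(iso), value = TRUE)
  iso[, zc] <- 0
  iso$z_rho_sugar <- 1
  cons <- parameterize_consumers(iso, fixture_substrates(2, seed = 5))
  oa <- cons$properties$class == "organic_acid"
  expect_true(all(cons$rho[oa, ] == 0))
  expect_true(all(cons$kinetics$N[oa, ] == 0))
  expect_true(all(cons$kinetics$Vmax[oa, ] == 0))
  sug <- cons$properties$class == "sugar"
  expect_true(all(cons$kinetics$Vmax[sug, ] > 0))
})

test_that("maintenance scales with cell volume and can be switched off", {
  cfg <- deb_config()
  k1 <- maintenance_rate(1, 5e13, cfg)
  # per-cell maintenance doubles with volume (lambda_B held fixed)
  expect_equal(maintenance_rate(2, 5e13, cfg), 2 * k1)
  expect_equal(k1, cfg$maintenance$kappa_M * 1 * 5e13)
  cfg0 <- deb_config(maintenance = list(kappa_M = 0))
  expect_equal(maintenance_rate(1.7, 5e13, cfg0), 0)
})

test_that("porter density solve is monotone in demand and self-consistent", {
  iso <- fixture_isolates(1, seed = 8)
  geom <- isolate_geometry(iso)
  sol <- solve_porter_density(geom)
  iso2 <- iso
  iso2$r_max <- iso$r_max * 2
  iso2$min_gen_time_h <- log(2) / iso2$r_max
  sol2 <- solve_porter_density(isolate_geometry(iso2))
  expect_gt(sol2$rho_total, sol$rho_total)
  # closure identity: k_E m_E* equals the saturation assimilation flux
  # p_Am = supply * (1 + m_E*) within the solver tolerance
  lhs <- geom$k_E * sol$m_E_star
  rhs <- sol$supply * (1 + sol$m_E_star)
  expect_equal(lhs, rhs, tolerance = 1e-6)
  # and the steady-state growth equation returns r_max
  cfg <- deb_config()
  r_at <- (geom$k_E * sol$m_E_star - geom$k_M) /
    (sol$m_E_star + geom$y_EV)
  expect_equal(r_at, geom$r_max, tolerance = 1e-4)
  expect_lte(sol$iterations, cfg$closure$fp_max_iter)
})

test_that("feasibility frontier: faster demand needs more membrane", {
  iso <- fixture_isolates(1, seed = 12)
  rhos <- vapply(c(0.02, 0.1, 0.3), function(rm) {
    iso$r_max <- rm
    iso$min_gen_time_h <- log(2) / rm
    solve_porter_density(isolate_geometry(iso))$rho_total
  }, numeric(1))
  expect_true(all(diff(rhos) > 0))
  # squeezing the packing limit makes fast growth infeasible
  cfg_tight <- deb_config(kinetics = list(rho_max = 1e-6))
  iso$r_max <- 0.4; iso$min_gen_time_h <- log(2) / 0.4
  expect_error(
    solve_porter_density(isolate_geometry(iso, cfg_tight),
                         reference_substrate(cfg_tight),
                         config = cfg_tight),
    "infeasible"
  )
})

test_that("solved porter densities land in a realistic range", {
  cons <- parameterize_consumers(fixture_isolates(12, seed = 4),
                                 fixture_substrates(2, seed = 4))
  rt <- cons$consumers$rho_total
  expect_true(all(rt > 0 & rt < 0.25))
  active <- cons$rho[cons$rho > 0]
  expect_gt(median(active), 1e-8)
  expect_lt(median(active), 0.01)
})

test_that("per-substrate closure mode solves every pair", {
  cons <- parameterize_consumers(fixture_isolates(2, seed = 6),
                                 fixture_substrates(1, seed = 6),
                                 rho_mode = "per_substrate")
  expect_true(all(is.finite(cons$rho)))
  expect_true(any(cons$rho > 0))
  # class weighting still applies
  td <- tidy(cons)
  expect_true(all(td$rho >= 0))
})
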