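test_that("RHS matches an independent literal transcription", {
  cons <- small_consumers()
  j <- 1
  si <- seq_len(nrow(cons$properties))
  parms <- rhizodeb:::.sim_parms(cons, si, j, deb_protocol())
  set.seed(31)
  for (k in 1:5) {
    D <- stats::runif(length(si), 0, 2e-3)
    E <- stats::runif(1, 1e-9, 1e-3)
    V <- stats::runif(1, 1e-9, 1e-3)
    y <- c(D, E, V, 0, 0, 0, 0)
    got <- rhizodeb:::.deb_rhs(0, y, parms)[[1]]
    # literal re-derivation, scalar loops only
    B_tot <- E + V
    oracle <- deb_rhs_oracle(D, E, V, list(
      a = parms$a, y_ED = parms$y_ED[, 1],
      K = parms$grid$K[, 1], N = parms$grid$N[, 1],
      Vmax = parms$grid$Vmax[, 1],
      k_E = parms$k_E, y_EV = parms$y_EV, k_M = parms$k_M,
      zeta = parms$zeta_X,
      gamma = parms$gamma0 * B_tot / parms$B_ref,
      omega = parms$omega
    ))
    expect_equal(got[seq_along(D)], oracle$dD, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(got[length(D) + 1], oracle$dE, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(got[length(D) + 2], oracle$dV, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(got[length(D) + 4], oracle$dCO2, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("starvation shrinks structure while respiring", {
  cons <- small_consumers()
  parms <- rhizodeb:::.sim_parms(cons, 1, 1, deb_protocol())
  y <- c(0, 0, 1e-6, 0, 0, 0, 0) # no substrate, no reserve
  d <- rhizodeb:::.deb_rhs(0, y, parms)[[1]]
  expect_lt(d[3], 0)  # dV/dt < 0
  expect_gt(d[5], 0)  # dCO2/dt > 0
})

test_that("growth equation limit: no maintenance, saturating substrate", {
  iso <- fixture_isolates(1, seed = 14)
  zc <- grep("^z_rho_", names(iso), value = TRUE)
  iso[, zc] <- 0; iso$z_rho_sugar <- 1; iso$z_X <- 0
  cfg <- deb_config(maintenance = list(kappa_M = 0),
                    turnover = list(gamma0 = 0))
  sub <- tibble::tibble(name = "glucose", class = "sugar",
                        formula = "C6H12O6", charge = 0)
  cons <- parameterize_consumers(iso, sub, cfg)
  parms <- rhizodeb:::.sim_parms(cons, 1, 1, deb_protocol())
  m_E <- 0.4; V <- 1e-5; E <- m_E * V
  y <- c(10, E, V, 0, 0, 0, 0) # vastly saturating substrate
  d <- rhizodeb:::.deb_rhs(0, y, parms)[[1]]
  cc <- cons$consumers
  r_hand <- cc$k_E * m_E / (m_E + cc$y_EV)
  expect_equal(d[3] / V, r_hand, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero inoculum stays flat with flagged CUE", {
  cons <- small_consumers()
  p0 <- deb_protocol(inoculum_cells = 0, t_batch = 10)
  s <- simulate_batch(cons, substrates = cons$properties$name[1],
                      isolates = cons$consumers$isolate_id[1], protocol = p0)
  expect_true(is.na(s$CUE))
  expect_true(is.na(s$r_realized))
  tr <- s$result[[1]]$trajectory
  expect_equal(tr$E, rep(0, nrow(tr)))
  expect_equal(max(abs(diff(tr[[2]]))), 0)
})

test_that("a fast grower on sugar shows a sigmoidal batch with exhaustion", {
  iso <- fixture_isolates(1, seed = 19)
  iso$r_max <- 0.35; iso$min_gen_time_h <- log(2) / 0.35
  zc <- grep("^z_rho_", names(iso), value = TRUE)
  iso[, zc] <- 0; iso$z_rho_sugar <- 1
  sub <- tibble::tibble(name = "glucose", class = "sugar",
                        formula = "C6H12O6", charge = 0)
  cons <- parameterize_consumers(iso, sub)
  s <- simulate_batch(cons)
  sim <- s$result[[1]]
  expect_lt(sim$summary$t_end, 500)
  expect_false(is.na(s$exhausted_at))
  tr <- sim$trajectory
  expect_true(all(diff(tr$V) > -1e-12 | tr$V[-1] < max(tr$V)))
  # structure ends orders of magnitude above the inoculum
  expect_gt(tail(tr$V, 1) / tr$V[1], 100)
  # depletion event recorded at the end of the run
  expect_equal(s$exhausted_at, sim$summary$t_end, tolerance = 1e-6)
  # carbon closes
  expect_lt(sim$summary$carbon_balance_error, 1e-6)
})

test_that("all pools stay non-negative and CUE lies in [0, 1]", {
  phen <- population_phenotypes()
  expect_true(all(phen$CUE >= 0 & phen$CUE <= 1, na.rm = TRUE))
  expect_true(all(phen$BP >= 0, na.rm = TRUE))
  one <- phen$result[[which.max(phen$BP)]]$trajectory
  pools <- one[, setdiff(names(one), c("t", "m_E", "r", "growth_rate"))]
  expect_true(all(as.matrix(pools) >= -1e-12))
})

test_that("realized growth never exceeds the reserve turnover ceiling", {
  phen <- population_phenotypes()
  cons <- parameterize_consumers(fixture_isolates(16, seed = 21),
                                 fixture_substrates(1, seed = 21))
  kE <- setNames(cons$consumers$k_E, cons$consumers$isolate_id)
  ok <- is.finite(phen$r_realized)
  expect_true(all(phen$r_realized[ok] <= kE[phen$isolate[ok]] + 1e-9))
})

test_that("tightening integrator tolerances leaves the budgets unchanged", {
  iso <- fixture_isolates(1, seed = 23)
  sub <- fixture_substrates(1, seed = 23)
  cons1 <- parameterize_consumers(iso, sub)
  cfg2 <- deb_config(integrator = list(rtol = 5e-9, atol = 5e-15))
  cons2 <- parameterize_consumers(iso, sub, cfg2)
  s_name <- cons1$properties$name[cons1$kinetics$Vmax[, 1] > 0][1]
  r1 <- simulate_batch(cons1, substrates = s_name)
  r2 <- simulate_batch(cons2, substrates = s_name)
  expect_equal(r1$BP, r2$BP, tolerance = 1e-4)
  expect_equal(r1$BR, r2$BR, tolerance = 1e-4)
  expect_equal(r1$CUE, r2$CUE, tolerance = 1e-4)
})

test_that("single-substrate mixed medium reduces to the batch protocol", {
  iso <- fixture_isolates(1, seed = 25)
  sub <- fixture_substrates(1, seed = 25)[1, ]
  cons <- parameterize_consumers(iso, sub)
  p <- deb_protocol(t_batch = 300, t_mixed = 300)
  b <- simulate_batch(cons, protocol = p)
  m <- simulate_mixed(cons, protocol = p)
  expect_equal(m$phenotypes$BP, b$BP, tolerance = 1e-10)
  expect_equal(m$phenotypes$BR, b$BR, tolerance = 1e-10)
  expect_equal(m$phenotypes$CUE, b$CUE, tolerance = 1e-10)
})

test_that("disjoint transporter complements deplete disjoint classes", {
  iso <- fixture_isolates(2, seed = 27)
  iso$r_max <- c(0.3, 0.25); iso$min_gen_time_h <- log(2) / iso$r_max
  zc <- grep("^z_rho_", names(iso), value = TRUE)
  iso[, zc] <- 0
  iso$z_rho_sugar <- c(1, 0)
  iso$z_rho_amino_acid <- c(0, 1)
  sub <- fixture_substrates(1, seed = 27)
  sub <- sub[sub$class %in% c("sugar", "amino_acid"), ]
  cons <- parameterize_consumers(iso, sub)
  mx <- simulate_mixed(cons, community = TRUE)
  led <- mx$ledger
  # joint-run ledger is per substrate: the sugar went down, and cross
  # fluxes are exactly zero in the kinetics grid
  expect_true(all(cons$kinetics$Vmax[sub$class == "amino_acid", 1] == 0))
  expect_true(all(cons$kinetics$Vmax[sub$class == "sugar", 2] == 0))
  expect_true(all(led$consumed >= 0))
  # per-isolate runs: each consumes only its own class
  mx2 <- simulate_mixed(cons)
  l1 <- mx2$ledger[mx2$ledger$isolate == "iso01", ]
  expect_true(all(l1$fraction[l1$class == "amino_acid"] < 1e-9))
  expect_gt(sum(l1$fraction[l1$class == "sugar"]), 0)
})

test_that("population growth rates occupy both documented regimes", {
  phen <- population_phenotypes()
  r <- phen$r_realized[is.finite(phen$r_realized) & phen$r_realized > 0]
  expect_gt(length(r), 40)
  # both regimes occupied, spanning slow soil-like and fast culture-like rates
  expect_gt(sum(r >= 0.039), 5)
  expect_gt(sum(r < 0.039), 5)
  expect_lt(min(r), 0.01)
  expect_gt(max(r), 0.1)
})

test_that("uptake ledger reconciles with the concentration differences", {
  cons <- small_consumers()
  mx <- simulate_mixed(cons, isolates = cons$consumers$isolate_id[1:2])
  for (nm in names(mx$results)) {
    sim <- mx$results[[nm]]
    led <- mx$ledger[mx$ledger$isolate == nm, ]
    expect_equal(sum(led$consumed),
                 sum(sim$substrates$D0 - sim$substrates$D_end),
                 tolerance = 1e-12)
    expect_lt(sim$summary$carbon_balance_error, 1e-6)
  }
})
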