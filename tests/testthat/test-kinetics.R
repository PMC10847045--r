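test_that("affinity reduces to K0 without binding sites and inflates linearly", {
  expect_equal(affinity(1e-4, 1e-20, 0, 6.7e-10, 5e-7, 1e10), 1e-4)
  # calculator-checked value
  K <- affinity(K0 = 1e-4, k_plus = 1e-20, B_total = 1e14, D = 6.7e-10,
                r_c = 5e-7, n_cell = 1e10)
  infl_hand <- 1e-20 * 1e4 / (4 * pi * 6.7e-10 * 5e-7)
  expect_equal(K, 1e-4 * (1 + infl_hand), tolerance = 1e-12)
  # doubling sites per cell doubles K/K0 - 1
  K2 <- affinity(1e-4, 1e-20, 2e14, 6.7e-10, 5e-7, 1e10)
  expect_equal((K2 / 1e-4 - 1) / (K / 1e-4 - 1), 2, tolerance = 1e-12)
})

test_that("biomass-specific binding sites are linear with a checked value", {
  expect_equal(binding_sites_per_molC(0, 5e-7, 3e-13), 0)
  n1 <- binding_sites_per_molC(0.001, 5e-7, 3e-13)
  expect_equal(binding_sites_per_molC(0.002, 5e-7, 3e-13), 2 * n1)
  hand <- 12.011 * 4 * pi * (5e-7)^2 * 0.001 /
    (0.47 * 3e-13 * pi * (1e-9)^2 * 6.02214076e23)
  expect_equal(n1, hand, tolerance = 1e-12)
})

test_that("single-pair ECA collapses to its scalar form and to MM", {
  cons <- small_consumers()
  g <- cons$kinetics
  pick <- which(g$N > 0, arr.ind = TRUE)[1, ]
  K <- g$K[pick[1], pick[2]]; N <- g$N[pick[1], pick[2]]
  Vm <- g$Vmax[pick[1], pick[2]]
  grid1 <- list(N = matrix(N), Vmax = matrix(Vm), K = matrix(K))
  D <- 0.05; B <- 1e-3
  j <- eca_fluxes(D, B, grid1)
  scalar <- -Vm * B * (D / K) / (1 + D / K + N * B * 1000 / K)
  expect_equal(j[1, 1], scalar, tolerance = 1e-12)
  # two identical consumers on one substrate split the flux of one with 2B
  grid2 <- list(N = cbind(N, N), Vmax = cbind(Vm, Vm), K = cbind(K, K))
  j2 <- eca_fluxes(D, c(B, B), grid2)
  jday <- eca_fluxes(D, 2 * B, grid1)
  expect_equal(j2[1, 1], j2[1, 2], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(j2[1, 1] + j2[1, 2], jday[1, 1], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("fluxes vanish with the substrate and never turn positive", {
  set.seed(101)
  inst <- random_eca_instance()
  while (length(inst$D) < 2) inst <- random_eca_instance()
  inst$D[1] <- 0
  grid <- list(N = inst$N, Vmax = inst$Vmax, K = inst$K)
  j <- eca_fluxes(inst$D, inst$B, grid)
  expect_true(all(j <= 0))
  expect_true(all(j[1, ] == 0))
  grid$N[2, ] <- 0; grid$Vmax[2, ] <- 0
  j2 <- eca_fluxes(inst$D, inst$B, grid)
  expect_true(all(j2[2, ] == 0))
  expect_error(eca_fluxes(-inst$D, inst$B, grid), "negative")
})

test_that("flux rises with substrate and falls with competitor biomass", {
  set.seed(7)
  inst <- random_eca_instance()
  while (nrow(inst$N) < 2 || length(inst$B) < 2) inst <- random_eca_instance()
  grid <- list(N = inst$N, Vmax = inst$Vmax, K = inst$K)
  u0 <- -eca_fluxes(inst$D, inst$B, grid)
  D2 <- inst$D; D2[1] <- D2[1] * 2
  u_up <- -eca_fluxes(D2, inst$B, grid)
  expect_gt(u_up[1, 1], u0[1, 1])
  B2 <- inst$B; B2[2] <- B2[2] * 10
  u_comp <- -eca_fluxes(inst$D, B2, grid)
  expect_lte(u_comp[1, 1], u0[1, 1])
})

test_that("trade-off curve has the correct limits", {
  cons <- small_consumers()
  props <- cons$properties[1, ]
  geom <- cons$consumers[1, ]
  rho_grid <- c(1e-6, 1e-4, 1e-3, 1e-2, 0.1)
  tc <- tradeoff_curve(props, geom, rho_grid)
  expect_true(all(diff(tc$Vmax) > 0))
  expect_true(all(diff(tc$K) > 0))
  # rho -> 0: Vmax -> 0, K -> K0
  K0 <- cons$kinetics$K0[1, 1]
  tc0 <- tradeoff_curve(props, geom, c(1e-12, 1e-10))
  expect_lt(tc0$Vmax[1], 1e-6)
  expect_equal(tc0$K[1], K0, tolerance = 1e-4)
  expect_error(tradeoff_curve(props, geom, c(0.3, 0.4)), "packing")
})
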