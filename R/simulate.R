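# Right-hand side of the DEB state equations.
#
# State layout: [D_1..D_I, then per consumer j: E, V, X, CO2, NEC, BP].
# Units: mol C per litre for all pools; time in hours. Uptake is computed on
# the substrate molar scale (mM) by the ECA network and converted at the
# boundary via the substrate carbon content a_i.
.deb_rhs <- function(t, y, p) {
  I <- p$I; J <- p$J
  D <- pmax(y[seq_len(I)], 0)
  cs <- matrix(y[-seq_len(I)], nrow = 6L) # E,V,X,CO2,NEC,BP by consumer
  E <- pmax(cs[1L, ], 0); V <- pmax(cs[2L, ], 0)
  B <- E + V
  D_mM <- D / p$a * 1000
  jsub <- eca_fluxes(D_mM, B, p$grid)    # mol substrate / L / h, <= 0
  u <- -jsub
  dD <- p$a * .rowSums(jsub, I, J)
  assim <- .colSums(p$y_ED * u, I, J)
  overhead_assim <- .colSums((rep(p$a, J) - p$y_ED) * u, I, J)
  live <- V > p$v_floor
  m_E <- ifelse(live, E / pmax(V, p$v_floor), 0)
  r <- (p$k_E * m_E - p$k_M) / (m_E + p$y_EV * (1 + p$zeta_X))
  gam <- p$gamma0 * sum(B) / p$B_ref
  dE <- dV <- dX <- dCO2 <- dNEC <- dBP <- numeric(J)
  grow <- live & r >= 0
  if (any(grow)) {
    g <- grow
    drain <- p$k_E[g] * m_E[g] * V[g] - m_E[g] * r[g] * V[g]
    dE[g] <- assim[g] - drain - gam * E[g]
    dV[g] <- r[g] * V[g] - gam * V[g]
    dX[g] <- p$zeta_X[g] * r[g] * V[g]
    dCO2[g] <- overhead_assim[g] +
      (p$y_EV[g] - 1) * (1 + p$zeta_X[g]) * r[g] * V[g] + p$k_M[g] * V[g]
    dNEC[g] <- gam * (E[g] + V[g])
    # gross biomass production: reserve synthesis (assimilation) plus
    # structural synthesis, before turnover subtraction
    dBP[g] <- assim[g] + r[g] * V[g]
  }
  starve <- live & r < 0
  if (any(starve)) {
    s <- starve
    mobil <- p$k_E[s] * m_E[s] * V[s]
    deficit <- pmax(p$k_M[s] * V[s] - mobil, 0)
    dE[s] <- assim[s] - mobil - gam * E[s]
    dV[s] <- -p$omega * deficit - gam * V[s]
    dCO2[s] <- overhead_assim[s] + mobil + p$omega * deficit
    dNEC[s] <- gam * (E[s] + V[s])
    dBP[s] <- assim[s]
  }
  list(c(dD, rbind(dE, dV, dX, dCO2, dNEC, dBP)))
}

.root_depletion <- function(t, y, p) {
  min(y[seq_len(p$I)]) - p$depletion_threshold
}

# Build the RHS parameter list for a subset of consumers/substrates.
.sim_parms <- function(consumers, sub_idx, cons_idx, protocol) {
  cfg <- consumers$config
  g <- consumers$kinetics
  grid <- list(
    N = g$N[sub_idx, cons_idx, drop = FALSE],
    Vmax = g$Vmax[sub_idx, cons_idx, drop = FALSE],
    K = g$K[sub_idx, cons_idx, drop = FALSE]
  )
  cc <- consumers$consumers[cons_idx, ]
  list(
    I = length(sub_idx), J = length(cons_idx),
    a = consumers$properties$a[sub_idx],
    grid = grid,
    y_ED = consumers$y_ED[sub_idx, cons_idx, drop = FALSE],
    k_E = cc$k_E, y_EV = cc$y_EV, k_M = cc$k_M, zeta_X = cc$zeta_X,
    gamma0 = cfg$turnover$gamma0, B_ref = cfg$turnover$B_ref,
    omega = cfg$integrator$starvation_overhead,
    v_floor = 1e-30,
    depletion_threshold = protocol$depletion_threshold
  )
}

.integrate_deb <- function(y0, t_max, parms, cfg, dt) {
  times <- unique(c(seq(0, t_max, by = dt), t_max))
  out <- deSolve::lsodar(
    y = y0, times = times, func = .deb_rhs, parms = parms,
    rootfunc = .root_depletion,
    rtol = cfg$integrator$rtol, atol = cfg$integrator$atol
  )
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out), arr.ind = TRUE)[1, 1]
    abort(paste0("integration produced non-finite state at t = ",
                 out[bad, 1], "; last state: ",
                 paste(signif(out[max(bad - 1, 1), -1], 4), collapse = ", ")))
  }
  out
}

# Assemble a deb_sim object from an integration of one consumer.
.build_sim <- function(out, parms, consumers, sub_idx, cons_idx, protocol,
                       initial_total) {
  I <- parms$I
  sub_names <- consumers$properties$name[sub_idx]
  cc <- consumers$consumers[cons_idx, ]
  Dm <- out[, 1 + seq_len(I), drop = FALSE]
  off <- 1 + I
  E <- out[, off + 1]; V <- out[, off + 2]; X <- out[, off + 3]
  CO2 <- out[, off + 4]; NEC <- out[, off + 5]; BP <- out[, off + 6]
  m_E <- ifelse(V > 0, E / V, NA_real_)
  r <- (cc$k_E * m_E - cc$k_M) / (m_E + cc$y_EV * (1 + cc$zeta_X))
  traj <- tibble(t = out[, 1])
  for (i in seq_len(I)) traj[[paste0("D_", sub_names[i])]] <- Dm[, i]
  traj$E <- E; traj$V <- V; traj$X <- X
  traj$CO2 <- CO2; traj$necromass <- NEC; traj$BP_cum <- BP
  traj$m_E <- m_E; traj$r <- r
  traj$growth_rate <- NA_real_ # filled below from total biomass
  total <- rowSums(Dm) + E + V + X + CO2 + NEC
  cbal <- max(abs(total - initial_total)) / initial_total
  n <- nrow(out)
  cfg <- consumers$config
  bp_gross <- BP[n]
  bp_net <- (E[n] + V[n] - E[1] - V[1]) + NEC[n]
  bp <- if (cfg$reporting$bp_mode == "net") bp_net else bp_gross
  br <- CO2[n]
  # realized growth: instantaneous specific growth rate of total biomass
  # (what a growth curve measures); summarized over the growth phase
  Bm <- E + V
  tt <- out[, 1]
  g_inst <- c(NA_real_, diff(log(pmax(Bm, 1e-300))) / diff(tt))
  floor_r <- cfg$integrator$growth_rate_floor
  growth_pts <- which(is.finite(g_inst) & g_inst > floor_r)
  r_real <- if (length(growth_pts)) {
    switch(cfg$reporting$r_metric,
           mean = mean(g_inst[growth_pts]),
           max = max(g_inst[growth_pts]),
           median(g_inst[growth_pts]))
  } else NA_real_
  traj$growth_rate <- g_inst
  co2_rate <- diff(CO2) / diff(out[, 1])
  latency <- if (length(co2_rate) && any(co2_rate > 0)) {
    mid <- (out[-1, 1] + out[-n, 1]) / 2
    mid[which.max(co2_rate)]
  } else NA_real_
  exhausted <- vapply(seq_len(I), function(i) {
    hit <- which(Dm[, i] <= protocol$depletion_threshold * 1.001)
    if (length(hit)) unname(out[hit[1], 1]) else NA_real_
  }, numeric(1))
  structure(
    list(
      trajectory = traj,
      isolate = cc$isolate_id,
      substrates = tibble(substrate = sub_names,
                          class = consumers$properties$class[sub_idx],
                          D0 = Dm[1, ], D_end = Dm[n, ],
                          exhausted_at = exhausted),
      summary = list(
        BP = bp, BR = br,
        BP_rate = bp / max(out[n, 1], .Machine$double.eps),
        BR_rate = br / max(out[n, 1], .Machine$double.eps),
        BP_gross = bp_gross, BP_net = bp_net,
        CUE = if (bp + br > 0) bp / (bp + br) else NA_real_,
        r_realized = unname(r_real),
        r_max_traj = suppressWarnings(max(g_inst[is.finite(g_inst)])),
        latency = unname(latency),
        t_end = unname(out[n, 1]),
        carbon_balance_error = unname(cbal)
      ),
      protocol = protocol
    ),
    class = "deb_sim"
  )
}

#' Simulate batch growth on single substrates
#'
#' Runs one batch culture per isolate-substrate pair: the substrate starts at
#' the protocol concentration (125 mg C per litre by default, optionally
#' scaled), the inoculum is split 90/10 between reserve and structure, and
#' the stiff ODE system is integrated until the horizon or substrate
#' exhaustion. Pairs with zero transporter allocation are still run (they
#' simply starve).
#'
#' @param consumers a `deb_consumers` object from [parameterize_consumers()].
#' @param substrates character vector of substrate names (default: all).
#' @param isolates character vector of isolate ids (default: all).
#' @param protocol a [deb_protocol()].
#' @param conc_scale multiplier on the protocol concentration (use e.g. 100
#'   for saturating-substrate experiments).
#' @return A tibble of class `deb_batch` with one row per pair: `isolate`,
#'   `substrate`, `class`, `response_group` (if present), `r_realized`,
#'   `CUE`, `BP`, `BR`, `latency`, `t_end`, `exhausted_at`,
#'   `carbon_balance_error`, and a list-column `result` of `deb_sim` objects.
#' @examples
#' cons <- parameterize_consumers(fixture_isolates(2, seed = 1),
#'                                fixture_substrates(1, seed = 1))
#' sims <- simulate_batch(cons, substrates = cons$properties$name[1])
#' sims[, c("isolate", "substrate", "r_realized", "CUE")]
#' @export
simulate_batch <- function(consumers, substrates = NULL, isolates = NULL,
                           protocol = deb_protocol(), conc_scale = 1) {
  stopifnot(inherits(consumers, "deb_consumers"))
  substrates <- substrates %||% consumers$properties$name
  isolates <- isolates %||% consumers$consumers$isolate_id
  sub_idx_all <- match(substrates, consumers$properties$name)
  cons_idx_all <- match(isolates, consumers$consumers$isolate_id)
  if (any(is.na(sub_idx_all))) abort("unknown substrate name")
  if (any(is.na(cons_idx_all))) abort("unknown isolate id")
  cfg <- consumers$config
  D0 <- conc_scale * protocol$conc_mgC / 1000 / .const$M_C # mol C / L
  grid_runs <- tidyr::expand_grid(ci = cons_idx_all, si = sub_idx_all)
  rows <- purrr::pmap(grid_runs, function(ci, si) {
    cc <- consumers$consumers[ci, ]
    B0 <- protocol$inoculum_cells * protocol$soil_g_per_l / cc$lambda_B
    y0 <- c(D0,
            protocol$reserve_fraction * B0,       # E
            (1 - protocol$reserve_fraction) * B0, # V
            0, 0, 0, 0)                           # X, CO2, NEC, BP
    parms <- .sim_parms(consumers, si, ci, protocol)
    out <- .integrate_deb(y0, protocol$t_batch, parms, cfg, protocol$dt)
    sim <- .build_sim(out, parms, consumers, si, ci, protocol, D0 + B0)
    tibble(
      isolate = cc$isolate_id,
      substrate = consumers$properties$name[si],
      class = consumers$properties$class[si],
      response_group = if ("response_group" %in% names(cc))
        cc$response_group else NA_character_,
      r_realized = sim$summary$r_realized,
      CUE = sim$summary$CUE,
      BP = sim$summary$BP,
      BR = sim$summary$BR,
      BP_rate = sim$summary$BP_rate,
      BR_rate = sim$summary$BR_rate,
      latency = sim$summary$latency,
      t_end = sim$summary$t_end,
      exhausted_at = sim$substrates$exhausted_at[1],
      carbon_balance_error = sim$summary$carbon_balance_error,
      result = list(sim)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("deb_batch", class(out))
  out
}

#' Simulate growth in a mixed medium
#'
#' The batch protocol extended to a mixed growth medium: the total substrate
#' concentration is split evenly across all metabolites and each isolate is
#' grown alone on the full mixture (set `community = TRUE` to let all
#' isolates compete in a single run). Integration stops at the horizon
#' (1,500 h by default) or when the first metabolite is depleted. The
#' returned uptake ledger records, per isolate and substrate, the consumed
#' concentration difference, its fraction of the initial supply, the share
#' `p` of the isolate's total consumption, and the Levins niche breadth.
#'
#' @param consumers a `deb_consumers` object.
#' @param isolates character vector of isolate ids (default: all).
#' @param protocol a [deb_protocol()].
#' @param community simulate all isolates together instead of one at a time.
#' @return A list of class `deb_mixed`: `ledger` (tidy uptake ledger),
#'   `phenotypes` (per-isolate CUE, realized rate, niche breadth) and
#'   `results` (named list of `deb_sim`).
#' @export
simulate_mixed <- function(consumers, isolates = NULL,
                           protocol = deb_protocol(), community = FALSE) {
  stopifnot(inherits(consumers, "deb_consumers"))
  isolates <- isolates %||% consumers$consumers$isolate_id
  cons_idx_all <- match(isolates, consumers$consumers$isolate_id)
  if (any(is.na(cons_idx_all))) abort("unknown isolate id")
  cfg <- consumers$config
  I <- nrow(consumers$properties)
  sub_idx <- seq_len(I)
  D0 <- rep(protocol$conc_mgC / 1000 / .const$M_C / I, I)
  run_one <- function(cons_idx) {
    cc <- consumers$consumers[cons_idx, , drop = FALSE]
    B0 <- protocol$inoculum_cells * protocol$soil_g_per_l / cc$lambda_B
    y0 <- c(D0, rbind(protocol$reserve_fraction * B0,
                      (1 - protocol$reserve_fraction) * B0,
                      0, 0, 0, 0))
    parms <- .sim_parms(consumers, sub_idx, cons_idx, protocol)
    out <- .integrate_deb(y0, protocol$t_mixed, parms, cfg, protocol$dt)
    if (length(cons_idx) == 1L) {
      .build_sim(out, parms, consumers, sub_idx, cons_idx, protocol,
                 sum(D0) + sum(B0))
    } else {
      .build_community_sim(out, parms, consumers, sub_idx, cons_idx,
                           protocol, sum(D0) + sum(B0))
    }
  }
  results <- if (community) {
    setNames(list(run_one(cons_idx_all)), "community")
  } else {
    setNames(purrr::map(cons_idx_all, run_one), isolates)
  }
  ledger <- purrr::imap(results, function(sim, nm) {
    subs <- if (inherits(sim, "deb_sim")) sim$substrates else sim$substrates
    consumed <- pmax(subs$D0 - subs$D_end, 0)
    tibble(
      isolate = if (inherits(sim, "deb_sim")) sim$isolate else nm,
      substrate = subs$substrate,
      class = subs$class,
      D0 = subs$D0, D_end = subs$D_end,
      consumed = consumed,
      fraction = consumed / subs$D0,
      p = if (sum(consumed) > 0) consumed / sum(consumed) else NA_real_
    )
  }) |> bind_rows()
  breadth <- ledger |>
    group_by(.data$isolate) |>
    summarise(niche_breadth = levins_index(.data$p), .groups = "drop")
  phen <- purrr::imap(results, function(sim, nm) {
    tibble(isolate = nm,
           r_realized = sim$summary$r_realized,
           CUE = sim$summary$CUE,
           BP = sim$summary$BP, BR = sim$summary$BR,
           latency = sim$summary$latency,
           t_end = sim$summary$t_end,
           carbon_balance_error = sim$summary$carbon_balance_error)
  }) |> bind_rows() |> left_join(breadth, by = "isolate")
  if ("response_group" %in% names(consumers$consumers)) {
    rg <- consumers$consumers |>
      select("isolate_id", "response_group")
    ledger <- left_join(ledger, rg, by = c(isolate = "isolate_id"))
    phen <- left_join(phen, rg, by = c(isolate = "isolate_id"))
  }
  structure(list(ledger = ledger, phenotypes = phen, results = results),
            class = "deb_mixed")
}

# community runs track the substrate ledger jointly; summaries are pooled
.build_community_sim <- function(out, parms, consumers, sub_idx, cons_idx,
                                 protocol, initial_total) {
  sim <- .build_sim_multi(out, parms, consumers, sub_idx, cons_idx, protocol,
                          initial_total)
  sim
}

.build_sim_multi <- function(out, parms, consumers, sub_idx, cons_idx,
                             protocol, initial_total) {
  I <- parms$I; J <- parms$J
  n <- nrow(out)
  sub_names <- consumers$properties$name[sub_idx]
  Dm <- out[, 1 + seq_len(I), drop = FALSE]
  states <- array(out[, (1 + I + 1):(1 + I + 6 * J)], dim = c(n, 6, J))
  CO2 <- rowSums(states[, 4, , drop = FALSE])
  BP <- rowSums(states[, 6, , drop = FALSE])
  total <- rowSums(Dm) + rowSums(states[, 1, , drop = FALSE]) +
    rowSums(states[, 2, , drop = FALSE]) + rowSums(states[, 3, , drop = FALSE]) +
    CO2 + rowSums(states[, 5, , drop = FALSE])
  structure(
    list(
      trajectory = tibble(t = out[, 1]),
      isolate = paste(consumers$consumers$isolate_id[cons_idx], collapse = "+"),
      substrates = tibble(substrate = sub_names,
                          class = consumers$properties$class[sub_idx],
                          D0 = Dm[1, ], D_end = Dm[n, ],
                          exhausted_at = NA_real_),
      summary = list(
        BP = BP[n], BR = CO2[n],
        CUE = if (BP[n] + CO2[n] > 0) BP[n] / (BP[n] + CO2[n]) else NA_real_,
        r_realized = NA_real_, r_max_traj = NA_real_, latency = NA_real_,
        t_end = unname(out[n, 1]),
        carbon_balance_error = unname(max(abs(total - initial_total)) /
                                        initial_total)
      ),
      protocol = protocol
    ),
    class = "deb_sim"
  )
}

#' @export
print.deb_sim <- function(x, ...) {
  s <- x$summary
  cat("<deb_sim> isolate ", x$isolate, " on ",
      paste(x$substrates$substrate, collapse = ", "), "\n", sep = "")
  cat(sprintf("  t_end %.1f h | CUE %.3f | r_realized %.4g h^-1 | BP %.3g | BR %.3g mol C/L\n",
              s$t_end, s$CUE, s$r_realized, s$BP, s$BR))
  invisible(x)
}

#' Tidy trajectory of a simulation
#'
#' @param x a `deb_sim` object.
#' @param ... unused.
#' @return A long tibble with columns `t`, `pool`, `value` covering substrate
#'   pools, reserve, structure, enzyme, CO2, necromass and reserve density.
#' @export
tidy.deb_sim <- function(x, ...) {
  x$trajectory |>
    tidyr::pivot_longer(-"t", names_to = "pool", values_to = "value")
}

#' One-row summary of a simulation
#'
#' @param x a `deb_sim` object.
#' @param ... unused.
#' @return A tibble with `isolate`, `BP`, `BR`, `CUE`, `r_realized`,
#'   `latency`, `t_end`, `carbon_balance_error`.
#' @export
glance.deb_sim <- function(x, ...) {
  s <- x$summary
  tibble(isolate = x$isolate, BP = s$BP, BR = s$BR, CUE = s$CUE,
         r_realized = s$r_realized, latency = s$latency, t_end = s$t_end,
         carbon_balance_error = s$carbon_balance_error)
}
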