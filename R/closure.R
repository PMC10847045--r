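#' Basal maintenance rate coefficient
#'
#' Maintenance is proportional to cell volume: the per-cell maintenance flux
#' `kappa_M * V_c` (mol C per cell per h) is converted to a biomass-specific
#' first-order coefficient via the cells-per-mol-C factor:
#' `k_M = kappa_M * V_c * lambda_B` (h^-1, per C-mol structure).
#'
#' @param V_c cell volume, um^3.
#' @param lambda_B cells per mol biomass C.
#' @param config a [deb_config()].
#' @return `k_M` in h^-1.
#' @export
maintenance_rate <- function(V_c, lambda_B, config = deb_config()) {
  stopifnot(all(V_c > 0), all(lambda_B > 0))
  config$maintenance$kappa_M * V_c * lambda_B
}

# Steady-state reserve density at saturating substrate for a supply rate
# s = y_ED * Vmax (C-mol reserve per C-mol biomass per h): with uptake
# proportional to total biomass C, dm_E/dt = s (1 + m_E) - k_E m_E, so
# m_E* = s / (k_E - s) (requires s < k_E).
.m_E_star <- function(s, k_E) {
  ifelse(s >= k_E, Inf, s / (k_E - s))
}

# supply rate y_ED(rho) * Vmax(rho) for the reference substrate, resolving the
# porter-cost -> y_ED fixed point (cost is linear in rho so this converges in
# one step; iterated defensively for configurable cost models)
.supply_rate <- function(rho, ref, geom, config) {
  thermo <- substrate_thermo(ref, rho, geom$r_c, geom$M_dry, config)
  N <- binding_sites_per_molC(rho, geom$r_c, geom$M_dry,
                              r_p = config$kinetics$r_p,
                              c_fraction = config$allometry$c_fraction)
  Vmax <- config$kinetics$k2 * 3600 * N
  thermo$y_ED * Vmax
}

#' Solve the supply-demand closure for total porter density
#'
#' Finds the total membrane area fraction `rho*` that a consumer must cover
#' with substrate binding sites so that, at saturating substrate, the
#' steady-state reserve density supports growth at the genome-inferred
#' maximum specific growth rate. Demand side: the reserve density required
#' for `r = r_max`,
#' `m_E_req = (r_max y_EV (1 + zeta_X) + k_M) / (k_E - r_max)`.
#' Supply side: at saturation the reserve density settles at
#' `m_E* = s/(k_E - s)` with `s = y_ED(rho) Vmax(rho)` the biomass-specific
#' assimilation rate; the maximum assimilation flux is then
#' `p_Am = k_E m_E*`, so the closure makes the reserve-capacity identity
#' `k_E = p_Am / m_E*` hold by construction. The root in `rho` is unique
#' because `s` is strictly increasing in `rho` (binding sites grow linearly;
#' the porter synthesis cost reduces `y_ED` only weakly); the porter-cost
#' feedback on `y_ED` is resolved by an inner fixed point.
#'
#' @param geom single-row isolate geometry table ([isolate_geometry()]).
#' @param reference single-row substrate property table used as the
#'   reference substrate (default: glucose).
#' @param zeta_X constitutive enzyme production coefficient.
#' @param config a [deb_config()].
#' @return A list with `rho_total`, `m_E_star`, `y_ED_ref`, `supply`,
#'   `iterations`.
#' @export
solve_porter_density <- function(geom, reference = NULL, zeta_X = 0,
                                 config = deb_config()) {
  stopifnot(nrow(geom) == 1)
  if (is.null(reference)) reference <- reference_substrate(config)
  r_max <- geom$r_max; k_E <- geom$k_E
  if (k_E <= r_max) {
    abort(paste0("infeasible phenotype for ", geom$isolate_id,
                 ": k_E (", format(k_E), ") must exceed r_max (",
                 format(r_max), ")"))
  }
  m_E_req <- (r_max * geom$y_EV * (1 + zeta_X) + geom$k_M) / (k_E - r_max)
  s_req <- k_E * m_E_req / (1 + m_E_req)
  rho_hi <- config$kinetics$rho_max * (1 - 1e-9)
  f <- function(rho) .supply_rate(rho, reference, geom, config) - s_req
  f_lo <- f(0); f_hi <- f(rho_hi)
  if (f_lo >= 0) {
    # demand met with vanishing porter area; return the root at ~0
    return(list(rho_total = 0, m_E_star = .m_E_star(.supply_rate(0, reference, geom, config), k_E),
                y_ED_ref = substrate_thermo(reference, 0, geom$r_c, geom$M_dry, config)$y_ED,
                supply = .supply_rate(0, reference, geom, config), iterations = 0L))
  }
  if (f_hi < 0) {
    abort(paste0(
      "infeasible phenotype for ", geom$isolate_id,
      ": r_max = ", format(r_max), " h^-1 unreachable for any membrane ",
      "allocation (required supply ", format(s_req),
      " C-mol C-mol^-1 h^-1, maximum ",
      format(.supply_rate(rho_hi, reference, geom, config)), ")"
    ))
  }
  root <- uniroot(f, c(0, rho_hi), tol = config$closure$tol * rho_hi)
  rho <- root$root
  # defensive fixed-point polish of the porter-cost feedback
  it <- 0L
  repeat {
    it <- it + 1L
    s <- .supply_rate(rho, reference, geom, config)
    if (abs(s - s_req) <= config$closure$fp_tol * s_req ||
        it >= config$closure$fp_max_iter) break
    rho <- uniroot(f, c(0, rho_hi), tol = config$closure$tol * rho_hi)$root
  }
  thermo <- substrate_thermo(reference, rho, geom$r_c, geom$M_dry, config)
  list(rho_total = rho, m_E_star = .m_E_star(s, k_E),
       y_ED_ref = thermo$y_ED, supply = s, iterations = it)
}

#' Reference substrate for the closure
#'
#' A glucose reference (C6H12O6, sugar class) with derived properties under
#' the given configuration; the closure solves the total porter density on
#' this substrate before allocation across classes.
#'
#' @param config a [deb_config()].
#' @return Single-row substrate property tibble.
#' @export
reference_substrate <- function(config = deb_config()) {
  substrate_properties(
    tibble(name = "glucose_reference", class = "sugar",
           formula = "C6H12O6", charge = 0),
    config
  )
}

#' Allocate total porter density across substrates
#'
#' Distributes a consumer's total porter area fraction over individual
#' substrates according to the relative transporter gene frequencies of the
#' substrate classes: `rho_i = rho_total * z_rho[class(i)] / n_class(i)`.
#' Classes absent from `z_rho` (or with zero frequency) receive zero
#' allocation; the total is conserved up to the mass of missing classes.
#'
#' @param rho_total total porter area fraction.
#' @param z_rho named numeric vector of per-class relative transporter gene
#'   frequencies (non-negative; normalized to sum 1 if not already).
#' @param classes character vector giving the class of each substrate.
#' @return Numeric vector of per-substrate area fractions.
#' @examples
#' allocate_porters(0.01, c(sugar = 0.5, amino_acid = 0.5),
#'                  c("sugar", "sugar", "amino_acid"))
#' @export
allocate_porters <- function(rho_total, z_rho, classes) {
  stopifnot(rho_total >= 0, all(z_rho >= 0))
  if (sum(z_rho) > 0) z_rho <- z_rho / sum(z_rho)
  counts <- table(classes)
  z <- z_rho[classes]
  z[is.na(z)] <- 0
  out <- rho_total * unname(z) / as.numeric(counts[classes])
  out
}

#' Parameterize consumers from trait and substrate tables
#'
#' The end-to-end trait translation: derives substrate properties and cell
#' geometry, solves the porter-density closure per isolate on the reference
#' substrate, allocates the total density across substrates via transporter
#' gene frequencies, evaluates per-substrate thermodynamic yields, and builds
#' the ECA kinetics grid.
#'
#' @param isolates isolate trait table (see [fixture_isolates()] for the
#'   expected columns; `z_rho_<class>` columns hold the per-class transporter
#'   gene frequencies).
#' @param substrates substrate table (see [fixture_substrates()]).
#' @param config a [deb_config()].
#' @param rho_mode `"reference"` (default): solve the total porter density
#'   once per isolate on the reference substrate, then distribute it across
#'   substrates via transporter gene frequencies; `"per_substrate"`
#'   (sensitivity mode): re-solve the density on every substrate and scale
#'   each solution by the normalized class frequency.
#' @return An object of class `deb_consumers`: a list with `consumers` (one
#'   row per isolate: geometry, `k_E`, `y_EV`, `k_M`, `zeta_X`, `rho_total`,
#'   `m_E_star`, `lambda_B`), `kinetics` (the `deb_kinetics` grid), `y_ED`
#'   (substrates x consumers matrix), `properties`, `rho` (allocation matrix)
#'   and the `config`.
#' @examples
#' cons <- parameterize_consumers(fixture_isolates(4, seed = 1),
#'                                fixture_substrates(1, seed = 1))
#' cons$consumers$rho_total
#' @export
parameterize_consumers <- function(isolates, substrates,
                                   config = deb_config(),
                                   rho_mode = c("reference",
                                                "per_substrate")) {
  rho_mode <- match.arg(rho_mode)
  properties <- if (all(c("nosc", "diffusivity", "dG_cat_Cmol", "a") %in%
                        names(substrates))) {
    as_tibble(substrates)
  } else {
    substrate_properties(substrates, config)
  }
  geometry <- if ("k_E" %in% names(isolates)) as_tibble(isolates) else
    isolate_geometry(isolates, config)
  zcols <- grep("^z_rho_", names(geometry), value = TRUE)
  if (!length(zcols)) abort("isolate table lacks z_rho_<class> columns")
  J <- nrow(geometry); I <- nrow(properties)
  geometry$zeta_X <- config$enzyme$zX_slope *
    (if ("z_X" %in% names(geometry)) geometry$z_X else 0)
  ref <- reference_substrate(config)
  closure <- purrr::map(seq_len(J), function(j) {
    solve_porter_density(geometry[j, ], ref, geometry$zeta_X[j], config)
  })
  geometry$rho_total <- purrr::map_dbl(closure, "rho_total")
  geometry$m_E_star <- purrr::map_dbl(closure, "m_E_star")
  rho <- matrix(0, I, J, dimnames = list(properties$name, geometry$isolate_id))
  y_ED <- matrix(0, I, J, dimnames = dimnames(rho))
  for (j in seq_len(J)) {
    z <- unlist(geometry[j, zcols])
    names(z) <- sub("^z_rho_", "", zcols)
    if (rho_mode == "reference") {
      rho[, j] <- allocate_porters(geometry$rho_total[j], z, properties$class)
    } else {
      zn <- if (sum(z) > 0) z / sum(z) else z
      rho_i <- vapply(seq_len(I), function(i) {
        solve_porter_density(geometry[j, ], properties[i, ],
                             geometry$zeta_X[j], config)$rho_total
      }, numeric(1))
      zi <- zn[properties$class]
      zi[is.na(zi)] <- 0
      rho[, j] <- rho_i * unname(zi)
    }
    y_ED[, j] <- substrate_thermo(properties, geometry$rho_total[j],
                                  geometry$r_c[j], geometry$M_dry[j],
                                  config)$y_ED
  }
  grid <- kinetics_grid(properties, geometry, rho, config)
  structure(
    list(consumers = geometry, kinetics = grid, y_ED = y_ED,
         properties = properties, rho = rho, config = config),
    class = c("deb_consumers", "list")
  )
}

#' Concentrate the full porter complement on one substrate
#'
#' Returns a copy of a parameterized consumer set in which every consumer's
#' entire solved porter area fraction is assigned to a single substrate
#' (kinetics rebuilt accordingly). This realizes exactly the configuration
#' assumed by the porter-density closure, and is the natural setting for
#' verifying that a consumer attains its genome-inferred maximum growth rate
#' at saturating substrate.
#'
#' @param consumers a `deb_consumers` object.
#' @param substrate substrate name receiving the full allocation (default:
#'   the first substrate).
#' @return A modified `deb_consumers` object.
#' @export
full_allocation_consumers <- function(consumers, substrate = NULL) {
  stopifnot(inherits(consumers, "deb_consumers"))
  substrate <- substrate %||% consumers$properties$name[1]
  i <- match(substrate, consumers$properties$name)
  if (is.na(i)) abort("unknown substrate name")
  rho <- consumers$rho * 0
  rho[i, ] <- consumers$consumers$rho_total
  consumers$rho <- rho
  consumers$kinetics <- kinetics_grid(consumers$properties,
                                      consumers$consumers, rho,
                                      consumers$config)
  consumers
}

#' @export
print.deb_consumers <- function(x, ...) {
  cat("<deb_consumers> ", nrow(x$consumers), " consumer(s) x ",
      nrow(x$properties), " substrate(s)\n", sep = "")
  cat("  total porter area fraction: ",
      paste(signif(range(x$consumers$rho_total), 3), collapse = " - "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy kinetic parameters of a parameterized consumer set
#'
#' One row per substrate-consumer pair with the quantities the uptake model
#' uses: porter allocation, binding sites, `Vmax`, `K0`, `K` and the
#' assimilation yield.
#'
#' @param x a `deb_consumers` object.
#' @param ... unused.
#' @return A tibble with columns `substrate`, `class`, `consumer`, `rho`,
#'   `N`, `Vmax`, `K0_mM`, `K_mM`, `y_ED`.
#' @export
tidy.deb_consumers <- function(x, ...) {
  g <- x$kinetics
  I <- nrow(g$N); J <- ncol(g$N)
  tibble(
    substrate = rep(rownames(g$N), J),
    class = rep(x$properties$class, J),
    consumer = rep(colnames(g$N), each = I),
    rho = as.vector(x$rho),
    N = as.vector(g$N),
    Vmax = as.vector(g$Vmax),
    K0_mM = as.vector(g$K0),
    K_mM = as.vector(g$K),
    y_ED = as.vector(x$y_ED)
  )
}

#' One-row summary of a parameterized consumer set
#'
#' @param x a `deb_consumers` object.
#' @param ... unused.
#' @return A tibble with counts and median kinetic parameters.
#' @export
glance.deb_consumers <- function(x, ...) {
  td <- tidy(x)
  active <- td |> filter(.data$rho > 0)
  tibble(
    n_consumers = nrow(x$consumers),
    n_substrates = nrow(x$properties),
    median_rho_substrate = median(active$rho),
    median_K_mM = median(active$K_mM),
    median_Vmax = median(active$Vmax),
    median_rho_total = median(x$consumers$rho_total)
  )
}
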