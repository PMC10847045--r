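#' Diffusion-limited substrate affinity
#'
#' Half-saturation constant of diffusive uptake by a spherical cell:
#' `K = K0 * (1 + k_plus * (B_total/n_cell) / (4 pi D r_c))`, where
#' `B_total/n_cell` is the number of binding sites per cell. The intrinsic
#' affinity `K0` is inflated by the competition of the cell's own binding
#' sites for the diffusive flux towards the cell; the inflation is linear in
#' sites per cell.
#'
#' @param K0 intrinsic half-saturation, mM.
#' @param k_plus forward binding rate coefficient, m^3 s^-1 per site.
#' @param B_total total binding site number density (same volume basis as
#'   `n_cell`).
#' @param D substrate diffusivity, m^2 s^-1.
#' @param r_c cell radius, m.
#' @param n_cell cell number density (same basis as `B_total`).
#' @return Affinity `K` in mM; equals `K0` when `B_total = 0`.
#' @export
affinity <- function(K0, k_plus, B_total, D, r_c, n_cell) {
  stopifnot(all(K0 > 0), all(k_plus > 0), all(B_total >= 0),
            all(D > 0), all(r_c > 0), all(n_cell > 0))
  K0 * (1 + k_plus * (B_total / n_cell) / (4 * pi * D * r_c))
}

#' Biomass-specific binding sites
#'
#' Number of substrate binding sites per mol of biomass carbon for a cell of
#' radius `r_c` whose surface carries transporters (cross-section radius
#' `r_p`) over an area fraction `rho_porter`:
#' `N = M_C * 4 pi r_c^2 * rho / (c_fraction * M_dry * pi r_p^2 * N_A)`.
#' Linear in `rho_porter`.
#'
#' @param rho_porter porter area fraction in `[0, 1)`.
#' @param r_c cell radius, m.
#' @param M_dry cell dry mass, g.
#' @param r_p transporter cross-section radius, m.
#' @param c_fraction carbon fraction of dry mass.
#' @return mol binding sites per mol biomass C.
#' @export
binding_sites_per_molC <- function(rho_porter, r_c, M_dry, r_p = 1e-9,
                                   c_fraction = 0.47) {
  stopifnot(all(rho_porter >= 0), all(rho_porter < 1),
            all(r_c > 0), all(M_dry > 0), r_p > 0)
  .const$M_C * 4 * pi * r_c^2 * rho_porter /
    (c_fraction * M_dry * pi * r_p^2 * .const$N_A)
}

# sites per cell implied by an area fraction: rho * 4 r_c^2 / r_p^2
.sites_per_cell <- function(rho_porter, r_c, r_p) {
  rho_porter * 4 * r_c^2 / r_p^2
}

# K per Eq-7 with per-cell sites: inflation k+ spc/(4 pi D r_c) = 4 rho r_c/r_p
.affinity_from_rho <- function(K0, rho_porter, r_c, r_p) {
  K0 * (1 + 4 * rho_porter * r_c / r_p)
}

#' Build the substrate-by-consumer kinetics grid
#'
#' Assembles the matrices the ECA flux network needs: biomass-specific
#' binding sites `N[i, j]`, maximum specific uptake rate
#' `Vmax[i, j] = k2 * N[i, j]` (mol substrate per mol C per h), intrinsic
#' affinity `K0[i, j] = k2 / (k_plus N_A)` (mM) with `k_plus = 4 pi D_i r_p`
#' the diffusion-limited encounter rate per site, and the inflated affinity
#' `K[i, j]` from the per-cell binding site count. Substrate classes without
#' transporter allocation get `N = Vmax = 0`.
#'
#' @param properties substrate property table ([substrate_properties()]).
#' @param geometry isolate geometry table ([isolate_geometry()]).
#' @param rho matrix of per-substrate porter area fractions
#'   (substrates x consumers).
#' @param config a [deb_config()].
#' @return A list of class `deb_kinetics` with matrices `N`, `Vmax`, `K0`,
#'   `K`, vector `a` (substrate C atoms), and dimnames from substrate and
#'   isolate ids.
#' @export
kinetics_grid <- function(properties, geometry, rho, config = deb_config()) {
  kin <- config$kinetics
  I <- nrow(properties); J <- nrow(geometry)
  stopifnot(is.matrix(rho), nrow(rho) == I, ncol(rho) == J)
  if (any(rho < 0)) abort("negative porter allocation")
  k_plus <- 4 * pi * properties$diffusivity * kin$r_p  # m^3 s^-1, per substrate
  K0_i <- kin$k2 / (k_plus * .const$N_A)               # mol m^-3 = mM
  N <- K0 <- K <- matrix(0, I, J,
                         dimnames = list(properties$name, geometry$isolate_id))
  for (j in seq_len(J)) {
    N[, j] <- binding_sites_per_molC(
      rho[, j], geometry$r_c[j], geometry$M_dry[j],
      r_p = kin$r_p, c_fraction = config$allometry$c_fraction
    )
    K0[, j] <- K0_i
    K[, j] <- .affinity_from_rho(K0_i, rho[, j], geometry$r_c[j], kin$r_p)
  }
  Vmax <- kin$k2 * 3600 * N
  structure(
    list(N = N, Vmax = Vmax, K0 = K0, K = K, rho = rho,
         a = setNames(properties$a, properties$name),
         k2 = kin$k2, r_p = kin$r_p),
    class = c("deb_kinetics", "list")
  )
}

#' ECA flux partitioning over a substrate-consumer network
#'
#' Equilibrium chemistry approximation fluxes for `I` substrates competing
#' for `J` consumers' binding sites and vice versa:
#' `j[i, j] = -Vmax[i, j] * B[j] * (D[i]/K[i, j]) / (1 + F_r[i] + F_c[j])`
#' with `F_c[j] = sum_l D[l]/K[l, j]` (substrates competing for consumer `j`)
#' and `F_r[i] = sum_l N[i, l] B[l] / K[i, l]` (consumers competing for
#' substrate `i`).
#'
#' @param D substrate concentrations, mM (length `I`).
#' @param B consumer biomasses, mol C per litre (length `J`).
#' @param grid a `deb_kinetics` grid from [kinetics_grid()].
#' @return Matrix of uptake fluxes (mol substrate per litre per h), `<= 0`
#'   for consumption; zero wherever `D[i] = 0` or `N[i, j] = 0`.
#' @export
eca_fluxes <- function(D, B, grid) {
  if (any(D < 0) || any(B < 0)) abort("negative concentrations in ECA network")
  I <- nrow(grid$N); J <- ncol(grid$N)
  stopifnot(length(D) == I, length(B) == J)
  DK <- D / grid$K                      # I x J (column recycling over D)
  Fc <- colSums(DK)                     # length J
  # binding-site concentration N*B (mol/L) on the mM scale of K
  NBK <- grid$N * rep(B * 1000, each = I) / grid$K
  Fr <- rowSums(NBK)                    # length I
  denom <- 1 + outer(Fr, Fc, "+")       # 1 + F_r[i] + F_c[j]
  -grid$Vmax * rep(B, each = I) * DK / denom
}

#' Uptake strategy trade-off curve
#'
#' Sweeps the porter area fraction for one substrate-consumer pair and
#' returns the induced maximum uptake rate, affinity and specific affinity
#' (`Vmax/K`, the low-concentration specific uptake rate). `Vmax` grows
#' linearly in `rho` while `K` inflates linearly, so the specific affinity
#' saturates: beyond area fractions of a few permille additional binding
#' sites buy almost no low-concentration advantage, and the `Vmax` vs `K`
#' frontier is (weakly) concave.
#'
#' @param properties single-row substrate property table.
#' @param geometry single-row isolate geometry table.
#' @param rho_grid increasing vector of porter area fractions.
#' @param config a [deb_config()].
#' @return A tibble of class `deb_tradeoff` with columns `rho`, `Vmax`
#'   (mol substrate per mol C per h), `K` (mM), `specific_affinity`.
#' @export
tradeoff_curve <- function(properties, geometry, rho_grid,
                           config = deb_config()) {
  stopifnot(nrow(properties) == 1, nrow(geometry) == 1)
  if (is.unsorted(rho_grid, strictly = TRUE)) {
    abort("rho_grid must be strictly increasing")
  }
  if (any(rho_grid < 0) || any(rho_grid >= config$kinetics$rho_max)) {
    abort("rho_grid must lie within [0, packing limit)")
  }
  kin <- config$kinetics
  k_plus <- 4 * pi * properties$diffusivity * kin$r_p
  K0 <- kin$k2 / (k_plus * .const$N_A)
  N <- binding_sites_per_molC(rho_grid, geometry$r_c, geometry$M_dry,
                              r_p = kin$r_p,
                              c_fraction = config$allometry$c_fraction)
  Vmax <- kin$k2 * 3600 * N
  K <- .affinity_from_rho(K0, rho_grid, geometry$r_c, kin$r_p)
  out <- tibble(
    rho = rho_grid,
    Vmax = Vmax,
    K = K,
    specific_affinity = ifelse(K > 0, Vmax / K, 0)
  )
  class(out) <- c("deb_tradeoff", class(out))
  out
}
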