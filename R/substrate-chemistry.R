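#' Parse an elemental formula in Hill notation
#'
#' Parses strings such as `"C6H12O6"` or `"C10H13N5O4"` into atom counts for
#' the four elements the model tracks (C, H, N, O).
#'
#' @param x character vector of formulas.
#' @return A tibble with columns `formula`, `a` (C), `b` (H), `c` (N), `d` (O).
#' @examples
#' parse_chem_formula("C6H12O6")
#' @export
parse_chem_formula <- function(x) {
  stopifnot(is.character(x))
  parse_one <- function(f) {
    if (is.na(f) || !nzchar(f)) abort("empty chemical formula")
    tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (!nzchar(gsub("([A-Z][a-z]?)([0-9]*)", "", f))) {
      counts <- c(C = 0, H = 0, N = 0, O = 0)
      for (p in parts) {
        el <- gsub("[0-9]", "", p)
        nn <- gsub("[^0-9]", "", p)
        nn <- if (nzchar(nn)) as.integer(nn) else 1L
        if (!el %in% names(counts)) {
          abort(paste0("unsupported element '", el, "' in formula '", f,
                       "' (only C, H, N, O are modelled)"))
        }
        counts[el] <- counts[el] + nn
      }
      counts
    } else {
      abort(paste0("cannot parse chemical formula '", f, "'"))
    }
  }
  m <- t(vapply(x, parse_one, numeric(4)))
  tibble(formula = x, a = m[, "C"], b = m[, "H"], c = m[, "N"], d = m[, "O"])
}

#' Nominal oxidation state of carbon
#'
#' NOSC of a molecule C_a H_b N_c O_d with net charge `z`, using the standard
#' charge-corrected definition `4 - (4a + b - 3c - 2d - z)/a`. Values outside
#' the physical range \[-4, 4\] indicate an impossible composition and raise
#' an error.
#'
#' @param a,b,c,d atom counts of C, H, N, O (vectorized).
#' @param z net charge (default 0).
#' @return Numeric vector of NOSC values.
#' @examples
#' nosc(6, 12, 0, 6)        # glucose: 0
#' nosc(2, 3, 0, 2, z = -1) # acetate: 0
#' @export
nosc <- function(a, b, c = 0, d = 0, z = 0) {
  n <- max(length(a), length(b), length(c), length(d), length(z))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n)
  d <- rep_len(d, n); z <- rep_len(z, n)
  if (any(a < 1)) abort("undefined composition: formula must contain carbon (a >= 1)")
  out <- 4 - (4 * a + b - 3 * c - 2 * d - z) / a
  bad <- !is.finite(out) | out < -4 | out > 4
  if (any(bad)) {
    abort(paste0("NOSC outside [-4, 4] for entry ", which(bad)[1],
                 " (", format(out[which(bad)[1]]), "): impossible composition"))
  }
  out
}

#' Aqueous diffusivity from molar mass
#'
#' Wilke-Chang correlation for dilute aqueous solutes, with the solute molar
#' volume at the normal boiling point estimated from molar mass and a fixed
#' organic-solute density (config `chemistry$solute_density`). Strictly
#' decreasing in molar mass at fixed temperature.
#'
#' @param molar_mass g per mol (vectorized).
#' @param temperature K.
#' @param config a [deb_config()].
#' @return Diffusivity in m^2 s^-1.
#' @examples
#' aqueous_diffusivity(180.16) # glucose-like, ~7e-10 m^2/s
#' @export
aqueous_diffusivity <- function(molar_mass,
                                temperature = NULL,
                                config = deb_config()) {
  if (any(!is.finite(molar_mass) | molar_mass <= 0)) {
    abort("molar_mass must be positive")
  }
  ch <- config$chemistry
  temperature <- temperature %||% ch$temperature
  stopifnot(temperature > 200, temperature < 400)
  V_A <- molar_mass / ch$solute_density # cm^3 per mol molar volume estimate
  # Wilke-Chang, water association factor 2.6, solvent M = 18.015 g/mol;
  # 7.4e-12 converts the cm^2/s form to m^2/s
  7.4e-12 * sqrt(2.6 * 18.015) * temperature / (ch$viscosity_cP * V_A^0.6)
}

#' Catabolic Gibbs energy of full aerobic oxidation
#'
#' Energy released per mol substrate when the carbon source is fully oxidized
#' with O2 as terminal electron acceptor, computed via the electron balance:
#' `(4 - NOSC) * a` electrons transferred, times a configurable energy per mol
#' electrons (`chemistry$energy_per_electron`, negative).
#'
#' @param a,b,c,d,z formula counts and net charge (vectorized).
#' @param config a [deb_config()].
#' @return kJ per mol substrate (negative for all viable electron donors).
#' @examples
#' catabolic_energy(6, 12, 0, 6) # glucose: 24 electrons
#' @export
catabolic_energy <- function(a, b, c = 0, d = 0, z = 0, config = deb_config()) {
  ns <- nosc(a, b, c, d, z)
  electrons <- (4 - ns) * a
  electrons * config$chemistry$energy_per_electron
}

#' Derive physicochemical substrate properties
#'
#' Takes a substrate table (one row per metabolite, columns `name`, `class`,
#' `formula`, `charge`, optionally `molar_mass`) and appends the derived
#' quantities the kinetics and thermodynamics modules consume: parsed atom
#' counts, molar mass (from the formula when absent), NOSC, electrons per
#' C-mol, aqueous diffusivity and the catabolic Gibbs energy (per mol and per
#' C-mol).
#'
#' @param substrates data frame of substrates.
#' @param config a [deb_config()].
#' @return A tibble with the input columns plus `a`, `b`, `c`, `d`,
#'   `molar_mass`, `nosc`, `electrons_per_Cmol`, `diffusivity`, `dG_cat`,
#'   `dG_cat_Cmol`.
#' @examples
#' substrate_properties(fixture_substrates(n_per_class = 1, seed = 1))
#' @export
substrate_properties <- function(substrates, config = deb_config()) {
  substrates <- as_tibble(substrates)
  req <- c("name", "class", "formula", "charge")
  missing_cols <- setdiff(req, names(substrates))
  if (length(missing_cols)) {
    abort(paste0("substrate table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  known <- c("sugar", "organic_acid", "amino_acid", "fatty_acid",
             "nucleotide", "auxin")
  bad_class <- setdiff(unique(substrates$class), known)
  if (length(bad_class)) {
    abort(paste0("unknown substrate class(es): ",
                 paste(bad_class, collapse = ", ")))
  }
  parsed <- parse_chem_formula(substrates$formula)
  out <- substrates |>
    mutate(a = parsed$a, b = parsed$b, c = parsed$c, d = parsed$d)
  am <- .const$atomic_mass
  mm_formula <- out$a * am["C"] + out$b * am["H"] + out$c * am["N"] +
    out$d * am["O"]
  if (!"molar_mass" %in% names(out)) {
    out$molar_mass <- unname(mm_formula)
  } else {
    out$molar_mass <- ifelse(is.na(out$molar_mass), unname(mm_formula),
                             out$molar_mass)
  }
  if (any(out$molar_mass <= 0)) abort("molar_mass must be positive")
  out |>
    mutate(
      nosc = nosc(.data$a, .data$b, .data$c, .data$d, .data$charge),
      electrons_per_Cmol = 4 - .data$nosc,
      diffusivity = aqueous_diffusivity(.data$molar_mass, config = config),
      dG_cat = .data$electrons_per_Cmol * .data$a *
        config$chemistry$energy_per_electron,
      dG_cat_Cmol = .data$dG_cat / .data$a
    )
}
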