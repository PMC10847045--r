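# Per-class metabolite templates (name, Hill formula, net charge). Organic
# and fatty acids are represented as the anions dominant at soil pH.
.substrate_templates <- list(
  sugar = tibble::tibble(
    name = c("glucose", "fructose", "galactose", "xylose", "arabinose",
             "ribose", "mannose", "sucrose", "trehalose", "maltose"),
    formula = c("C6H12O6", "C6H12O6", "C6H12O6", "C5H10O5", "C5H10O5",
                "C5H10O5", "C6H12O6", "C12H22O11", "C12H22O11", "C12H22O11"),
    charge = 0
  ),
  organic_acid = tibble::tibble(
    name = c("acetate", "lactate", "succinate", "malate", "citrate",
             "oxalate", "shikimate", "salicylate", "caffeate", "nicotinate"),
    formula = c("C2H3O2", "C3H5O3", "C4H4O4", "C4H4O5", "C6H5O7",
                "C2O4", "C7H9O5", "C7H5O3", "C9H7O4", "C6H4NO2"),
    charge = c(-1, -1, -2, -2, -3, -2, -1, -1, -1, -1)
  ),
  amino_acid = tibble::tibble(
    name = c("glycine", "alanine", "serine", "valine", "leucine",
             "proline", "threonine", "glutamate", "aspartate", "lysine",
             "phenylalanine", "tryptophan"),
    formula = c("C2H5NO2", "C3H7NO2", "C3H7NO3", "C5H11NO2", "C6H13NO2",
                "C5H9NO2", "C4H9NO3", "C5H8NO4", "C4H6NO4", "C6H14N2O2",
                "C9H11NO2", "C11H12N2O2"),
    charge = c(0, 0, 0, 0, 0, 0, 0, -1, -1, 0, 0, 0)
  ),
  fatty_acid = tibble::tibble(
    name = c("butyrate", "caproate", "caprylate", "laurate", "palmitate",
             "oleate"),
    formula = c("C4H7O2", "C6H11O2", "C8H15O2", "C12H23O2", "C16H31O2",
                "C18H33O2"),
    charge = -1
  ),
  nucleotide = tibble::tibble(
    name = c("adenosine", "guanosine", "cytidine", "uridine", "inosine",
             "thymidine"),
    formula = c("C10H13N5O4", "C10H13N5O5", "C9H13N3O5", "C9H12N2O6",
                "C10H12N4O5", "C10H14N2O5"),
    charge = 0
  ),
  auxin = tibble::tibble(
    name = c("indole3_acetate", "indole3_butyrate", "abscisate",
             "phenylacetate"),
    formula = c("C10H8NO2", "C12H12NO2", "C15H19O4", "C8H7O2"),
    charge = -1
  )
)

#' Generate a synthetic substrate table
#'
#' Deterministic (seeded) sampler over small per-class template sets of real
#' metabolite formulas (hexoses and disaccharides, C2-C9 organic acid anions,
#' proteinogenic amino acids, fatty acid anions, nucleosides, auxins), so the
#' class structure of NOSC and molecular size is realistic. When more
#' substrates per class are requested than a class has templates, templates
#' are recycled with a numeric suffix.
#'
#' @param n_per_class substrates drawn per class (single number or named
#'   vector over classes).
#' @param seed integer seed; the seed fully determines the table.
#' @return A tibble with columns `name`, `class`, `formula`, `charge`.
#' @examples
#' fixture_substrates(n_per_class = 2, seed = 42)
#' @export
fixture_substrates <- function(n_per_class = 2, seed = 1) {
  classes <- names(.substrate_templates)
  if (length(n_per_class) == 1L) {
    n_per_class <- setNames(rep(n_per_class, length(classes)), classes)
  }
  stopifnot(all(n_per_class >= 1))
  withr_seed(seed, {
    purrr::map(classes, function(cl) {
      tpl <- .substrate_templates[[cl]]
      n <- n_per_class[[cl]]
      reps <- ceiling(n / nrow(tpl))
      pool <- do.call(rbind, lapply(seq_len(reps), function(k) {
        t2 <- tpl
        if (k > 1) t2$name <- paste0(t2$name, "_", k)
        t2
      }))
      idx <- sample(nrow(pool), n)
      pool[sort(idx), ] |> mutate(class = cl, .after = "name")
    }) |> bind_rows()
  })
}

#' Generate a synthetic isolate trait table
#'
#' Deterministic (seeded) generator of genome-derived trait tables emulating
#' a rhizosphere isolate collection: genome sizes of 2-10 Mbp, 1-15 rRNA
#' operon copies, minimum generation times spanning fast and slow growth
#' (maximum specific growth rates of roughly 0.005-0.45 h^-1, anticorrelated
#' with generation time through the operon count), Dirichlet-distributed
#' transporter gene frequencies over the six substrate classes, and
#' genome-size-normalized glycoside hydrolase frequencies. Group contrasts
#' mirror observed rhizosphere response patterns: positive responders carry
#' more organic-acid/auxin transporters, fewer rRNA operons (slower maximum
#' growth) and fewer glycoside hydrolases; negative responders the reverse,
#' with sugar/amino-acid transporter bias.
#'
#' @param n number of isolates.
#' @param seed integer seed.
#' @param fractions named fractions of positive/negative/undefined
#'   responders (must sum to 1).
#' @param z_concentration Dirichlet concentration scaling for transporter
#'   frequencies (larger = less variable).
#' @return A tibble with columns `isolate_id`, `response_group`,
#'   `genome_size`, `rrn_copies`, `min_gen_time_h`, `r_max`, `z_X`, and one
#'   `z_rho_<class>` column per substrate class (rows sum to 1).
#' @examples
#' fixture_isolates(n = 5, seed = 7)
#' @export
fixture_isolates <- function(n = 24, seed = 1,
                             fractions = c(positive = 0.45, negative = 0.25,
                                           undefined = 0.30),
                             z_concentration = 6) {
  if (n < 1) abort("n must be >= 1")
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  classes <- names(.substrate_templates)
  bias <- list(
    positive  = c(sugar = 0.8, organic_acid = 3.0, amino_acid = 1.0,
                  fatty_acid = 0.8, nucleotide = 0.6, auxin = 2.0),
    negative  = c(sugar = 3.0, organic_acid = 0.6, amino_acid = 2.2,
                  fatty_acid = 0.8, nucleotide = 1.4, auxin = 0.3),
    undefined = c(sugar = 1.3, organic_acid = 1.3, amino_acid = 1.3,
                  fatty_acid = 1.0, nucleotide = 1.0, auxin = 0.8)
  )
  withr_seed(seed, {
    grp <- sample(rep(names(fractions),
                      times = diff(round(cumsum(c(0, fractions)) * n))))
    grp <- rep_len(grp, n)
    rrn <- vapply(grp, function(g) {
      switch(g,
             positive = sample(1:6, 1, prob = 6:1),
             negative = sample(4:15, 1, prob = c(1:6, 6:1)),
             undefined = sample(1:15, 1))
    }, numeric(1))
    # minimum generation time: log-linear in log(rrn), 1 copy ~ slow
    # (~150 h), 15 copies ~ fast (~1.5 h), with lognormal scatter
    log_t <- log(150) - (log(150) - log(1.5)) * log(rrn) / log(15)
    tmin <- exp(log_t + stats::rnorm(n, 0, 0.35))
    tmin <- pmin(pmax(tmin, 1.5), 160)
    genome <- vapply(grp, function(g) {
      switch(g,
             positive = stats::runif(1, 2e6, 8e6),
             negative = stats::runif(1, 4e6, 1e7),
             undefined = stats::runif(1, 2e6, 1e7))
    }, numeric(1))
    z_X <- vapply(grp, function(g) {
      switch(g,
             positive = stats::runif(1, 0, 0.02),
             negative = stats::runif(1, 0.02, 0.06),
             undefined = stats::runif(1, 0, 0.05))
    }, numeric(1))
    z <- t(vapply(grp, function(g) {
      alpha <- bias[[g]] * z_concentration / sum(bias[[g]])
      draw <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
      draw / sum(draw)
    }, numeric(length(classes))))
    colnames(z) <- paste0("z_rho_", classes)
    out <- tibble(
      isolate_id = sprintf("iso%02d", seq_len(n)),
      response_group = grp,
      genome_size = genome,
      rrn_copies = rrn,
      min_gen_time_h = tmin,
      r_max = log(2) / tmin,
      z_X = z_X
    )
    bind_cols(out, as_tibble(z))
  })
}

# run code under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
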