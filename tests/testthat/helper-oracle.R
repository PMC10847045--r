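# Independent oracles: literal, loop-by-loop transcriptions of the flux
# network and growth equations, kept deliberately naive and separate from the
# package's vectorized implementations.

# ECA flux network, substrate i x consumer j:
#   j_D[i,j] = -k2 N[i,j] B[j] * Fc_ij / (1 + Fr_i + Fc_j)
#   Fc_j = sum_l D[l]/K[l,j],  Fr_i = sum_l N[i,l] B_mM[l]/K[i,l]
# D and K in mM; B in mol C/L (sites N*B converted to mM).
eca_oracle <- function(D, B, K, N, Vmax) {
  I <- length(D); J <- length(B)
  out <- matrix(0, I, J)
  for (i in seq_len(I)) {
    for (j in seq_len(J)) {
      Fc_j <- 0
      for (l in seq_len(I)) Fc_j <- Fc_j + D[l] / K[l, j]
      Fr_i <- 0
      for (l in seq_len(J)) Fr_i <- Fr_i + N[i, l] * B[l] * 1000 / K[i, l]
      Fc_ij <- D[i] / K[i, j]
      out[i, j] <- -Vmax[i, j] * B[j] * Fc_ij / (1 + Fr_i + Fc_j)
    }
  }
  out
}

# random ECA instance generator (dimensions <= 5 x 4)
random_eca_instance <- function() {
  I <- sample(1:5, 1); J <- sample(1:4, 1)
  list(
    D = stats::runif(I, 0, 5),
    B = stats::runif(J, 0, 1e-2),
    K = matrix(10^stats::runif(I * J, -5, -1), I, J),
    N = matrix(10^stats::runif(I * J, -9, -6), I, J),
    Vmax = matrix(stats::runif(I * J, 0, 1), I, J)
  )
}

# literal transcription of the growth equation and carbon bookkeeping for a
# single consumer on multiple substrates; returns named derivative list
deb_rhs_oracle <- function(D_molC, E, V, pars) {
  # pars: a, y_ED (vector), K (mM), N, Vmax, k_E, y_EV, k_M, zeta, gamma,
  # omega
  I <- length(D_molC)
  D_mM <- D_molC / pars$a * 1000
  u <- numeric(I)
  Fc <- sum(D_mM / pars$K)
  for (i in seq_len(I)) {
    Fr_i <- pars$N[i] * (E + V) * 1000 / pars$K[i]
    u[i] <- pars$Vmax[i] * (E + V) * (D_mM[i] / pars$K[i]) / (1 + Fr_i + Fc)
  }
  assim <- sum(pars$y_ED * u)
  m_E <- if (V > 0) E / V else 0
  r <- (pars$k_E * m_E - pars$k_M) / (m_E + pars$y_EV * (1 + pars$zeta))
  if (r >= 0) {
    drain <- pars$k_E * m_E * V - m_E * r * V
    dE <- assim - drain - pars$gamma * E
    dV <- r * V - pars$gamma * V
    dX <- pars$zeta * r * V
    dCO2 <- sum((pars$a - pars$y_ED) * u) +
      (pars$y_EV - 1) * (1 + pars$zeta) * r * V + pars$k_M * V
    dNEC <- pars$gamma * (E + V)
  } else {
    mobil <- pars$k_E * m_E * V
    deficit <- max(pars$k_M * V - mobil, 0)
    dE <- assim - mobil - pars$gamma * E
    dV <- -pars$omega * deficit - pars$gamma * V
    dX <- 0
    dCO2 <- sum((pars$a - pars$y_ED) * u) + mobil + pars$omega * deficit
    dNEC <- pars$gamma * (E + V)
  }
  list(dD = -pars$a * u, dE = dE, dV = dV, dX = dX, dCO2 = dCO2,
       dNEC = dNEC, r = r)
}
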