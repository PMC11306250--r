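# Linear mechanics of the three-bead assay.
#
# Coordinates x = (x1 driven bead, x2 passive bead, xa actin rod), all nm,
# measured from the unloaded trap centres.  Each bead feels its trap and a
# linker to the rod; when the motor is attached the rod additionally feels
# kappa_state * (xa - stroke).  The system is a 3-coordinate overdamped
# Ornstein-Uhlenbeck process: Gamma dx = -(K x - b(t)) dt + sqrt(2 kT Gamma) dW.

motor_states <- c("detached", "post1_ADP", "rigor")

state_kappa <- function(mech, state) {
  switch(state,
         detached = 0,
         post1_ADP = mech$kappa_pre,
         rigor = mech$kappa_rigor,
         stop("unknown state: ", state, call. = FALSE))
}

state_stroke <- function(mech, state) {
  switch(state,
         detached = 0,
         post1_ADP = mech$ws1,
         rigor = mech$ws1 + mech$ws2,
         stop("unknown state: ", state, call. = FALSE))
}

#' Stiffness matrix of the bead-dumbbell network
#'
#' @param mech a [mech_params()] object.
#' @param state one of `"detached"`, `"post1_ADP"`, `"rigor"`.
#' @return 3x3 stiffness matrix over (driven bead, passive bead, actin rod),
#'   pN nm^-1.
#' @export
network_stiffness <- function(mech, state = "detached") {
  kt <- mech$kappa_trap; kl <- mech$kappa_link
  ks <- state_kappa(mech, state)
  matrix(c(kt + kl, 0,       -kl,
           0,       kt + kl, -kl,
           -kl,     -kl,     2 * kl + ks), 3, 3, byrow = TRUE)
}

network_drag <- function(mech) {
  gb <- bead_drag(mech)
  diag(c(gb, gb, mech$gamma_rod))
}

# Constant part of the drive vector b: trap offsets and stroke anchor.
network_drive <- function(mech, state, static_offset = 0) {
  kt <- mech$kappa_trap
  ks <- state_kappa(mech, state)
  s <- state_stroke(mech, state)
  c(kt * static_offset, kt * static_offset, ks * s)
}

#' Static equilibrium of the network
#'
#' Solves `K x = b` for the mean bead/rod positions given the motor state,
#' its stroke offset and a common static offset of both trap centres, and
#' returns the crossbridge load (resisting positive).
#'
#' @inheritParams network_stiffness
#' @param static_offset common displacement of both trap centres (nm).
#' @return List with `x` (positions, nm), `extension` (crossbridge extension
#'   `xa - stroke`, nm) and `load` (`kappa_state * (stroke - xa)`, pN).
#' @export
static_equilibrium <- function(mech, state = "detached", static_offset = 0) {
  K <- network_stiffness(mech, state)
  b <- network_drive(mech, state, static_offset)
  x <- drop(solve(K, b))
  ks <- state_kappa(mech, state)
  s <- state_stroke(mech, state)
  list(x = x, extension = x[3] - s, load = ks * (s - x[3]))
}

# Crossbridge load contributed by the static trap offset alone, i.e. with the
# stroke-induced self-load subtracted out.
offset_load <- function(mech, state, static_offset) {
  if (state == "detached" || static_offset == 0) return(0)
  static_equilibrium(mech, state, static_offset)$load -
    static_equilibrium(mech, state, 0)$load
}

#' Series-compliance attenuation of the working stroke
#'
#' Ratio of the passive-bead displacement to the motor stroke at static
#' equilibrium: the fraction of the stroke that survives the series
#' compliance of crossbridge, linkers and traps.
#'
#' @inheritParams network_stiffness
#' @export
series_compliance_factor <- function(mech, state = "rigor") {
  s <- state_stroke(mech, state)
  if (s == 0) stop("state has no stroke offset", call. = FALSE)
  static_equilibrium(mech, state)$x[2] / s
}

#' Stationary covariance of the thermal motion
#'
#' Equipartition covariance `kT * K^-1` of the (instantaneously sampled)
#' network coordinates.
#'
#' @inheritParams network_stiffness
#' @param kT thermal energy (pN nm).
#' @export
network_covariance <- function(mech, state = "detached", kT = 4.07) {
  kT * solve(network_stiffness(mech, state))
}

#' Frequency response of the network to trap forcing
#'
#' Complex amplitudes of (x1, x2, xa) per unit amplitude of a sinusoidal
#' displacement of the driven trap centre: `X = (K + i w Gamma)^-1 kappa_trap e1`.
#'
#' @inheritParams network_stiffness
#' @param freq forcing frequency (Hz).
#' @export
network_transfer <- function(mech, state = "detached", freq = 100) {
  K <- network_stiffness(mech, state)
  G <- network_drag(mech)
  drop(solve(K + 2i * pi * freq * G, c(mech$kappa_trap, 0, 0)))
}

# expm(-Gamma^-1 K t) via the symmetrised eigenproblem; K SPD, Gamma diagonal.
network_propagator <- function(mech, state, dt) {
  K <- network_stiffness(mech, state)
  g <- diag(network_drag(mech))
  gi <- 1 / sqrt(g)
  S <- K * tcrossprod(gi)          # Gamma^-1/2 K Gamma^-1/2
  e <- eigen(S, symmetric = TRUE)
  ew <- exp(-e$values * dt)
  Phi <- (gi * e$vectors) %*% (ew * t(e$vectors * sqrt(g)))
  Phi
}

# Per-state precomputation for the exact one-step Gaussian propagator:
# Phi = expm(A dt), Q = Sigma - Phi Sigma Phi', mean drive terms.
ou_state_terms <- function(mech, state, dt, kT, static_offset = 0,
                           forcing_freq = 100, forcing_amp = 0) {
  K <- network_stiffness(mech, state)
  Phi <- network_propagator(mech, state, dt)
  Sigma <- kT * solve(K)
  Q <- Sigma - Phi %*% Sigma %*% t(Phi)
  Q <- (Q + t(Q)) / 2
  cholQ <- t(chol(Q))
  xc <- drop(solve(K, network_drive(mech, state, static_offset)))
  if (forcing_amp > 0) {
    G <- network_drag(mech)
    w <- 2 * pi * forcing_freq
    X <- drop(solve(K + 1i * w * G, c(mech$kappa_trap * forcing_amp / 2, 0, 0)))
  } else {
    X <- complex(real = c(0, 0, 0))
  }
  list(Phi = Phi, cholQ = cholQ, Sigma = Sigma, xc = xc,
       Xr = Re(X), Xi = Im(X))
}

#' Covariance of block-averaged samples
#'
#' Analytic covariance of the decimated output of the network simulator:
#' internal samples at step `dt` are block-averaged in groups of `navg`.
#' Used as the closed-form oracle for equipartition checks on simulated
#' traces.
#'
#' @inheritParams network_covariance
#' @param dt internal integration step (s).
#' @param navg samples per output block.
#' @export
decimated_covariance <- function(mech, state = "detached", kT = 4.07,
                                 dt = 2e-5, navg = 10) {
  Sigma <- network_covariance(mech, state, kT)
  Phi <- network_propagator(mech, state, dt)
  acc <- navg * Sigma
  P <- diag(3)
  for (l in seq_len(navg - 1)) {
    P <- P %*% Phi
    C <- P %*% Sigma
    acc <- acc + (navg - l) * (C + t(C))
  }
  acc / navg^2
}

# Dirichlet attenuation of a sinusoid under block averaging of navg points
# spaced dt apart.
block_average_gain <- function(freq, dt, navg) {
  x <- pi * freq * dt
  if (x == 0) return(1)
  sin(navg * x) / (navg * sin(x))
}
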