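# Entropic term of the binding free energy: interaction entropy (IE,
# exponential average of interaction-energy fluctuations) and normal-mode
# (NM) vibrational entropy at the molecular-mechanics level.

#' Interaction entropy from an interaction-energy series
#'
#' Computes \eqn{-T\Delta S = k_B T \ln \langle e^{\Delta E / k_B T} \rangle}
#' where \eqn{\Delta E = E - \langle E \rangle} is the fluctuation of the
#' receptor-ligand interaction energy.  \eqn{k_B T} is interpreted per mole
#' (RT, with R = 1.9858775e-3 kcal/K/mol) since all pipeline energies are
#' molar.  Evaluated by log-sum-exp, so it cannot overflow.  The estimate is
#' non-negative for any series (Jensen) and zero only for a constant series.
#' A diagnostic warning is raised when the fluctuation exceeds 3 RT, where
#' the exponential average converges poorly.
#'
#' @param series Numeric vector of interaction energies, kcal/mol (n >= 2).
#' @param temperature K (> 0), default 303.15.
#' @return A `bir3_entropy` list: `minus_T_dS` (kcal/mol), `method` ("IE"),
#'   `temperature`, `n_samples`, `sigma` (fluctuation SD, kcal/mol).
#' @export
interaction_entropy <- function(series, temperature = 303.15) {
  if (length(series) < 2) abort("interaction entropy needs at least 2 samples")
  if (temperature <= 0) abort("temperature must be > 0")
  if (any(!is.finite(series))) abort("non-finite values in energy series")
  rt <- .const$R_gas * temperature
  de <- series - mean(series)
  x <- de / rt
  m <- max(x)
  lse <- m + log(mean(exp(x - m)))     # log of the exponential average
  sigma <- stats::sd(de)
  if (sigma > 3 * rt) {
    warn(sprintf(paste0(
      "interaction-entropy fluctuation sigma = %.2f kcal/mol exceeds 3 RT ",
      "(%.2f): the exponential average converges slowly and the estimate ",
      "may be dominated by rare frames"), sigma, 3 * rt))
  }
  structure(list(minus_T_dS = rt * lse, method = "IE",
                 temperature = temperature, n_samples = length(series),
                 sigma = sigma),
            class = "bir3_entropy")
}

#' @export
print.bir3_entropy <- function(x, ...) {
  cat(sprintf("<bir3_entropy> -T dS = %.4f kcal/mol [%s, T = %g K]\n",
              x$minus_T_dS, x$method, x$temperature))
  invisible(x)
}

#' Harmonic toy force field
#'
#' Bonds and angles only: \eqn{E = \sum \frac12 k_b (r - r_0)^2 + \sum
#' \frac12 k_a (\theta - \theta_0)^2}, so `k` is the curvature at the
#' minimum (a diatomic with bond constant k vibrates at
#' \eqn{\omega = \sqrt{k/\mu}}).  Returns an energy
#' function of a flat coordinate vector, suitable for
#' [normal_mode_entropy()].  NM on full protein force fields is out of
#' scope; this keeps the energy model pluggable while exercising the whole
#' minimize/Hessian/eigenmode machinery.
#'
#' @param bonds Data frame `i`, `j` (1-based atom positions), `k`
#'   (kcal/mol/A^2), `r0` (A).
#' @param angles Optional data frame `i`, `j`, `k_atom`, `k` (kcal/mol/rad^2),
#'   `theta0` (radians); `j` is the vertex.
#' @return Function `f(xyz_vector) -> energy`.
#' @export
harmonic_ff <- function(bonds, angles = NULL) {
  force(bonds); force(angles)
  function(xv) {
    crd <- matrix(xv, ncol = 3, byrow = TRUE)
    e <- 0
    for (b in seq_len(nrow(bonds))) {
      d <- crd[bonds$i[b], ] - crd[bonds$j[b], ]
      e <- e + 0.5 * bonds$k[b] * (sqrt(sum(d^2)) - bonds$r0[b])^2
    }
    if (!is.null(angles)) {
      for (a in seq_len(nrow(angles))) {
        v1 <- crd[angles$i[a], ] - crd[angles$j[a], ]
        v2 <- crd[angles$k_atom[a], ] - crd[angles$j[a], ]
        ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        th <- acos(pmin(pmax(ct, -1), 1))
        e <- e + 0.5 * angles$k[a] * (th - angles$theta0[a])^2
      }
    }
    e
  }
}

#' @keywords internal
.num_gradient <- function(f, x, step = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- x[i] + step
    xm <- x; xm[i] <- x[i] - step
    g[i] <- (f(xp) - f(xm)) / (2 * step)
  }
  g
}

#' Normal-mode analysis and vibrational entropy
#'
#' Minimizes the energy to a gradient RMS below `grad_tol`, builds the
#' mass-weighted Hessian by central finite differences (step `fd_step`),
#' diagonalizes it, removes the 6 near-zero translational/rotational modes
#' (5 for a linear species), and accumulates the quantum
#' harmonic-oscillator entropy per retained mode at `temperature`.
#'
#' @param energy_fn Energy function of a flat coordinate vector (kcal/mol),
#'   e.g. from [harmonic_ff()].
#' @param coords Starting `n x 3` coordinates.
#' @param masses Atomic masses, amu (length n).
#' @param temperature K.
#' @param grad_tol Gradient RMS convergence threshold, kcal/mol/A.
#' @param fd_step Hessian finite-difference step, A.
#' @param linear Is the species linear (5 external modes)?  Default decides
#'   from the eigenvalue spectrum: n <= 2 atoms or a detected extra
#'   near-zero mode.
#' @param zero_tol Frequency below which a mode counts as external, cm^-1.
#' @return A `bir3_nm` list: sorted `frequencies` (cm^-1),
#'   `n_zero_modes_removed`, `s_vib` (kcal/mol/K), `minimized_energy`,
#'   `gradient_rms`.
#' @export
normal_mode_entropy <- function(energy_fn, coords, masses,
                                temperature = 303.15, grad_tol = 1e-5,
                                fd_step = 1e-4, linear = NULL, zero_tol = 1) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(masses) != n || any(masses <= 0)) {
    abort("masses must be positive and match the atom count")
  }
  x0 <- as.numeric(t(coords))
  gr <- function(x) .num_gradient(energy_fn, x)
  opt <- stats::optim(x0, energy_fn, gr = gr, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  # polish with a second pass if needed
  for (pass in 1:3) {
    g <- gr(opt$par)
    if (sqrt(mean(g^2)) <= grad_tol) break
    opt <- stats::optim(opt$par, energy_fn, gr = gr, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-15))
  }
  g <- gr(opt$par)
  grms <- sqrt(mean(g^2))
  if (grms > grad_tol) {
    abort(sprintf("minimization did not converge (gradient RMS %.2e)", grms))
  }
  x <- opt$par
  m3 <- rep(masses, each = 3)
  nf <- length(x)
  H <- matrix(0, nf, nf)
  for (i in seq_len(nf)) {
    xp <- x; xp[i] <- x[i] + fd_step
    xm <- x; xm[i] <- x[i] - fd_step
    H[, i] <- (.num_gradient(energy_fn, xp) - .num_gradient(energy_fn, xm)) /
      (2 * fd_step)
  }
  H <- (H + t(H)) / 2
  Hmw <- H / sqrt(outer(m3, m3))
  ev <- eigen(Hmw, symmetric = TRUE, only.values = TRUE)$values
  # eigenvalues in kcal/mol/A^2/amu; convert to cm^-1 (imaginary -> negative)
  freqs <- sign(ev) * .const$freq_conv * sqrt(abs(ev))
  freqs <- sort(freqs)
  n_external <- if (!is.null(linear)) {
    if (linear) 5L else 6L
  } else if (n <= 2) 5L else {
    # count near-zero modes actually present (6 nonlinear, 5 linear)
    nz <- sum(abs(freqs) < zero_tol)
    if (nz >= 6) 6L else 5L
  }
  n_external <- min(n_external, length(freqs))
  external <- order(abs(freqs))[seq_len(n_external)]
  retained <- freqs[-external]
  if (any(retained < -zero_tol)) {
    abort(sprintf("imaginary frequency %.1f cm^-1 after minimization: not at a minimum",
                  min(retained)))
  }
  retained <- retained[retained > zero_tol]
  s_vib <- sum(vapply(retained, qho_entropy, numeric(1),
                      temperature = temperature))
  structure(list(frequencies = retained, all_frequencies = freqs,
                 n_zero_modes_removed = n_external, s_vib = s_vib,
                 minimized_energy = opt$value, gradient_rms = grms,
                 temperature = temperature),
            class = "bir3_nm")
}

#' Quantum harmonic-oscillator entropy of one mode
#'
#' \eqn{S = R [ x/(e^x - 1) - \ln(1 - e^{-x}) ]} with
#' \eqn{x = h c \tilde\nu / k_B T}.
#'
#' @param freq Frequency, cm^-1 (> 0).
#' @param temperature K.
#' @return Entropy, kcal/(mol K).
#' @export
qho_entropy <- function(freq, temperature = 303.15) {
  if (freq <= 0) abort("mode frequency must be > 0")
  x <- .const$c2 * freq / temperature
  .const$R_gas * (x / (expm1(x)) - log1p(-exp(-x)))
}

#' Normal-mode estimate of the binding entropy term
#'
#' \eqn{-T\Delta S = -T (S_{complex} - S_{receptor} - S_{ligand})},
#' averaged over strided trajectory frames.  Each species is minimized
#' under its own energy function (single-trajectory extraction: species
#' coordinates come from the complex frame).
#'
#' @param traj A `bir3_trajectory`.
#' @param energy_fns List with elements `complex`, `receptor`, `ligand`,
#'   each an energy function of the species' flat coordinate vector.
#' @param stride Frame stride (>= 1).
#' @param temperature K.
#' @return A `bir3_entropy` (method "NM").
#' @export
nm_binding_entropy <- function(traj, energy_fns, stride = 1,
                               temperature = 303.15) {
  idx <- seq(1, n_frames(traj), by = stride)
  top <- traj$topology
  sp <- split_complex(top)
  vals <- vapply(idx, function(i) {
    f <- traj$frames[[i]]
    s_c <- normal_mode_entropy(energy_fns$complex, f, top$mass,
                               temperature = temperature)$s_vib
    s_r <- if (nrow(sp$receptor) >= 2) {
      normal_mode_entropy(energy_fns$receptor, f[sp$receptor_idx, , drop = FALSE],
                          sp$receptor$mass, temperature = temperature)$s_vib
    } else 0
    s_l <- if (nrow(sp$ligand) >= 2) {
      normal_mode_entropy(energy_fns$ligand, f[sp$ligand_idx, , drop = FALSE],
                          sp$ligand$mass, temperature = temperature)$s_vib
    } else 0
    -temperature * (s_c - s_r - s_l)
  }, numeric(1))
  structure(list(minus_T_dS = mean(vals), method = "NM",
                 temperature = temperature, n_samples = length(vals),
                 per_frame = vals),
            class = "bir3_entropy")
}
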