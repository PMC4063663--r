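#' @title Langevin / NVE / umbrella dynamics
#' @description
#' Integrates the structure-based model in reduced units (time in reduced
#' time, dt = 0.005 by default; temperature in epsilon with k_B = 1; masses
#' 1). Production sampling uses BAOAB Langevin dynamics whose friction is
#' gamma = 1/coupling, with the stochastic-dynamics time constant
#' `coupling = 2` as the default thermostat setting. NVE velocity-Verlet is
#' provided as an integrator validation mode, and umbrella runs add a
#' harmonic bias on a differentiable (logistic-switch) fraction of native
#' contacts.
#' @name md-engine
NULL

#' Run configuration
#'
#' @param temperature target temperature, epsilon.
#' @param n_steps number of integration steps.
#' @param dt time step, reduced time.
#' @param coupling stochastic-dynamics time constant tau_t; friction is
#'   gamma = 1/coupling.
#' @param stride store every `stride`-th frame.
#' @param seed integer seed; the trajectory is reproducible given the seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(temperature = 1.0, n_steps = 10000, dt = 0.005,
                       coupling = 2, stride = 100, seed = 1) {
  stopifnot(dt > 0, stride >= 1, n_steps >= 1, coupling > 0)
  structure(list(temperature = temperature, n_steps = as.integer(n_steps),
                 dt = dt, coupling = coupling, stride = as.integer(stride),
                 seed = as.integer(seed)),
            class = "run_config")
}

new_trajectory <- function(raw, topology, cfg, bias = NULL, mode) {
  structure(list(
    frames = raw$frames,            # F x 3n, nm
    times = raw$times,
    e_pot = raw$e_pot, e_kin = raw$e_kin,
    Q = raw$Q, Q_smooth = raw$Q_smooth, e_bias = raw$e_bias,
    x_final = raw$x_final, v_final = raw$v_final,
    n = topology$n, temperature = cfg$temperature, dt = cfg$dt,
    stride = cfg$stride, seed = cfg$seed, bias = bias, mode = mode
  ), class = "plasso_traj")
}

#' @export
print.plasso_traj <- function(x, ...) {
  cat("# trajectory: ", nrow(x$frames), " frames, ", x$n, " residues, T = ",
      x$temperature, " eps, dt = ", x$dt, ", mode ", x$mode,
      if (!is.null(x$bias)) {
        paste0(", umbrella Q0 = ", x$bias$q_center, " k = ", x$bias$k_umb)
      },
      "\n", sep = "")
  invisible(x)
}

#' Per-frame log of a trajectory as a tibble
#'
#' @param x a `plasso_traj`.
#' @param ... unused.
#' @return tibble with `frame`, `time`, `e_pot`, `e_kin`, `Q`, `Q_smooth`,
#'   `e_bias`, `temperature`.
#' @exportS3Method tibble::as_tibble
as_tibble.plasso_traj <- function(x, ...) {
  tibble::tibble(
    frame = seq_along(x$times), time = x$times,
    e_pot = x$e_pot, e_kin = x$e_kin,
    Q = x$Q, Q_smooth = x$Q_smooth, e_bias = x$e_bias,
    temperature = x$temperature
  )
}

#' Coordinates of one frame
#'
#' @param traj a `plasso_traj`.
#' @param frame frame index.
#' @return n x 3 matrix, nm.
#' @export
traj_frame <- function(traj, frame) {
  matrix(traj$frames[frame, ], ncol = 3, byrow = TRUE)
}

check_start <- function(topology, x0, e_max = 1e4) {
  if (!all(is.finite(x0))) stop("non-finite starting coordinates")
  e <- sbm_energy(topology, x0)
  if (!is.finite(e$total) || e$repulsive > e_max) {
    stop("starting structure is clash-ridden (repulsive energy ",
         signif(e$repulsive, 3), " eps)")
  }
  invisible(e)
}

run_core <- function(topology, x0, cfg, mode, q_center = 0, k_umb = 0,
                     q_lambda = 1.2, v0 = NULL) {
  check_start(topology, x0)
  set.seed(cfg$seed)
  if (is.null(v0)) {
    v0 <- if (mode == "nve" && cfg$temperature == 0) {
      matrix(0, topology$n, 3)
    } else {
      matrix(stats::rnorm(3 * topology$n, sd = sqrt(cfg$temperature)),
             topology$n, 3)
    }
  }
  gamma <- if (mode == "nve") 0 else 1 / cfg$coupling
  raw <- cpp_run_md(unclass(topology), x0, v0, cfg$dt, gamma,
                    cfg$temperature, cfg$n_steps, cfg$stride,
                    if (mode == "nve") 1L else 0L,
                    q_center, k_umb, q_lambda, 8L, 0.3)
  raw
}

#' Langevin (BAOAB) production run
#'
#' @param topology an `sbm_topology`.
#' @param x0 starting coordinates (n x 3, nm); defaults to the native state.
#' @param cfg a [run_config()].
#' @return a `plasso_traj`.
#' @export
run_langevin <- function(topology, x0 = NULL, cfg = run_config()) {
  if (is.null(x0)) x0 <- topology$x_native
  raw <- run_core(topology, x0, cfg, "langevin")
  new_trajectory(raw, topology, cfg, mode = "langevin")
}

#' NVE velocity-Verlet run (integrator validation)
#'
#' With `temperature = 0` in the config the initial velocities are zero;
#' otherwise they are drawn from Maxwell-Boltzmann at the configured
#' temperature and the total energy is then conserved.
#'
#' @inheritParams run_langevin
#' @param v0 optional explicit initial velocities (n x 3).
#' @return a `plasso_traj`.
#' @export
run_nve <- function(topology, x0 = NULL, cfg = run_config(), v0 = NULL) {
  if (is.null(x0)) x0 <- topology$x_native
  raw <- run_core(topology, x0, cfg, "nve", v0 = v0)
  new_trajectory(raw, topology, cfg, mode = "nve")
}

#' Umbrella-sampling run biased along Q
#'
#' Adds 0.5 k_umb (Q_s(x) - Q_center)^2 where Q_s is a differentiable
#' contact fraction (logistic switch of width 0.1 r0 at lambda r0 per
#' contact). The bias energy is recorded per frame for WHAM unbiasing; the
#' sharp contact-count Q is recorded alongside.
#'
#' @inheritParams run_langevin
#' @param q_center bias centre in [0, 1].
#' @param k_umb bias strength, epsilon.
#' @param q_lambda contact-formation tolerance factor for both the smooth
#'   switch position and the sharp count.
#' @return a `plasso_traj` with `bias` metadata.
#' @export
run_umbrella <- function(topology, x0 = NULL, cfg = run_config(),
                         q_center = 0.5, k_umb = 50, q_lambda = 1.2) {
  if (q_center < 0 || q_center > 1) stop("q_center must be in [0, 1]")
  if (k_umb < 0) stop("k_umb must be non-negative")
  if (nrow(topology$contacts) == 0) stop("umbrella run needs native contacts")
  if (is.null(x0)) x0 <- topology$x_native
  raw <- run_core(topology, x0, cfg, "langevin", q_center, k_umb, q_lambda)
  new_trajectory(raw, topology, cfg,
                 bias = list(q_center = q_center, k_umb = k_umb,
                             q_lambda = q_lambda),
                 mode = "umbrella")
}

#' Unfolded (extended-coil) starting coordinates
#'
#' An open, contact-free conformation that respects the covalent topology:
#' when the model carries an oxidized or dynamic disulphide, the loop
#' residues are laid out as a loose open ring (the covalent loop exists in
#' the unfolded state too) and the tails extend away from it; otherwise the
#' whole chain is a loose corkscrew. A short bonded-terms-only Langevin
#' relaxation (contacts switched off) settles bond lengths and residual
#' overlaps; the result is deterministic given `seed`.
#'
#' @param topology an `sbm_topology`.
#' @param seed RNG seed for the relaxation burst.
#' @return n x 3 matrix, nm.
#' @export
extended_coil <- function(topology, seed = 1) {
  n <- topology$n
  ij <- topology$bridge
  closed <- !is.null(ij) && topology$state %in% c("oxidized", "dynamic")

  # tight corkscrew: consecutive spacing ~bond length, backbone angles well
  # away from straight, no pair within contact range
  corkscrew <- function(m, origin, axis, phase = 0) {
    axis <- axis / sqrt(sum(axis^2))
    ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- ref - sum(ref * axis) * axis
    u <- u / sqrt(sum(u^2))
    v <- c(axis[2] * u[3] - axis[3] * u[2], axis[3] * u[1] - axis[1] * u[3],
           axis[1] * u[2] - axis[2] * u[1])
    k <- seq_len(m) - 1
    ang <- phase + 0.9 * k
    t(vapply(seq_len(m), function(s) {
      origin + axis * 0.26 * k[s] +
        0.32 * (cos(ang[s]) * u + sin(ang[s]) * v)
    }, numeric(3)))
  }

  x <- if (!closed) {
    corkscrew(n, c(0, 0, 0), c(0, 0, 1))
  } else {
    i <- ij[1]; j <- ij[2]
    nl <- j - i + 1
    R <- max(nl * 0.26 / (2 * pi), 0.8)
    phi <- (seq_len(nl) - 1) * 0.26 / R
    psi <- 0.9 * (seq_len(nl) - 1)
    ring <- cbind((R + 0.32 * cos(psi)) * cos(phi),
                  (R + 0.32 * cos(psi)) * sin(phi),
                  0.32 * sin(psi))
    out <- matrix(0, n, 3)
    out[i:j, ] <- ring
    if (i > 1) {
      nhat <- c(cos(phi[1]), sin(phi[1]), 0)
      ax <- c(0.3 * nhat[1], 0.3 * nhat[2], -1)
      out[(i - 1):1, ] <- corkscrew(i - 1, ring[1, ] + 0.3 * ax, ax)
    }
    if (j < n) {
      nhat <- c(cos(phi[nl]), sin(phi[nl]), 0)
      ax <- c(0.3 * nhat[1], 0.3 * nhat[2], 1)
      out[(j + 1):n, ] <- corkscrew(n - j, ring[nl, ] + 0.3 * ax, ax)
    }
    out
  }

  # relax bonds and overlaps only; contacts off so the coil stays unfolded.
  # displacement-capped steepest descent is robust to arbitrarily bad
  # initial overlaps (forces may be enormous)
  relax <- unclass(topology)
  relax$contacts <- matrix(numeric(0), 0, 5)
  relax$angles <- matrix(numeric(0), 0, 5)
  relax$dihedrals <- matrix(numeric(0), 0, 7)
  set.seed(seed)
  x <- x + matrix(stats::rnorm(3 * n, sd = 1e-4), n, 3)
  for (it in seq_len(400)) {
    f <- cpp_sbm_forces(relax, x)
    fmax <- max(sqrt(rowSums(f^2)))
    if (fmax < 50) break
    x <- x + f * (0.02 / fmax)
  }
  x
}

#' Write the per-frame log to TSV
#'
#' @param traj a `plasso_traj`.
#' @param path output file.
#' @export
write_traj_log <- function(traj, path) {
  utils::write.table(as_tibble.plasso_traj(traj), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
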