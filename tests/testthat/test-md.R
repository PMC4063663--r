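# a soft two-bead spring: analytically solvable subsystem for thermostat checks
soft_spring_topology <- function(k = 100, r0 = 1.0) {
  structure(list(
    n = 2L,
    bonds = matrix(c(1, 2, r0, k), 1, 4),
    angles = matrix(0, 0, 5), dihedrals = matrix(0, 0, 7),
    contacts = matrix(0, 0, 5), rep_excl = matrix(0L, 0, 2),
    sigma = 0.4, eps_rep = 1, rcut = 1.2, min_rep_sep = 999L,
    state = "reduced", bridge = NULL, eps_ss = 1, width = 0.05,
    x_native = rbind(c(0, 0, 0), c(r0, 0, 0)),
    contact_map = tibble::tibble(i = integer(), j = integer(), r0 = numeric())
  ), class = "sbm_topology")
}

test_that("Langevin sampling matches Boltzmann on a harmonic bond", {
  tp <- soft_spring_topology(k = 100)
  cfg <- run_config(temperature = 1.0, n_steps = 2e5, stride = 10, seed = 2)
  tr <- run_langevin(tp, tp$x_native, cfg)
  r <- sqrt((tr$frames[, 4] - tr$frames[, 1])^2 +
              (tr$frames[, 5] - tr$frames[, 2])^2 +
              (tr$frames[, 6] - tr$frames[, 3])^2)
  r <- r[-(1:2000)]
  # V = (k/2)(r-r0)^2 at r0 >> fluctuation: var(r) ~ T/k
  expect_equal(var(r), 1 / 100, tolerance = 0.1)
  # mean kinetic temperature within 2% (soft system, no stiff-mode bias)
  tkin <- mean(2 * tr$e_kin[-(1:2000)] / (3 * 2))
  expect_equal(tkin, 1.0, tolerance = 0.02)
})

test_that("zero-friction Langevin reduces to velocity-Verlet", {
  fx <- fx_pierced_C14()
  cfg0 <- run_config(temperature = 0, n_steps = 50, stride = 1, seed = 3,
                     coupling = 1e9)
  set.seed(3)
  v0 <- matrix(rnorm(3 * fx$ox$n, sd = 0.3), fx$ox$n, 3)
  lan <- plasso:::run_core(fx$ox, fx$ox$x_native, cfg0, "langevin", v0 = v0)
  nve <- plasso:::run_core(fx$ox, fx$ox$x_native, cfg0, "nve", v0 = v0)
  expect_equal(lan$frames, nve$frames, tolerance = 1e-8)
})

test_that("trajectories are reproducible given the seed", {
  fx <- fx_pierced_C14()
  cfg <- run_config(temperature = 0.7, n_steps = 2000, stride = 100, seed = 5)
  a <- run_langevin(fx$ox, fx$ox$x_native, cfg)
  b <- run_langevin(fx$ox, fx$ox$x_native, cfg)
  expect_identical(a$frames, b$frames)
  cfg2 <- run_config(temperature = 0.7, n_steps = 2000, stride = 100, seed = 6)
  expect_false(identical(run_langevin(fx$ox, fx$ox$x_native, cfg2)$frames,
                         a$frames))
})

test_that("velocity-Verlet is time-reversible", {
  fx <- fx_pierced_C14()
  set.seed(11)
  v0 <- matrix(rnorm(3 * fx$ox$n, sd = sqrt(0.05)), fx$ox$n, 3)
  fwd <- run_nve(fx$ox, fx$ox$x_native,
                 run_config(temperature = 0.05, n_steps = 64, stride = 64),
                 v0 = v0)
  back <- run_nve(fx$ox, fwd$x_final,
                  run_config(temperature = 0.05, n_steps = 64, stride = 64),
                  v0 = -fwd$v_final)
  expect_lt(max(abs(back$x_final - fx$ox$x_native)), 1e-9)
})

test_that("a rigidly translating free chain conserves energy exactly", {
  tp <- soft_spring_topology(k = 50, r0 = 0.38)
  v0 <- matrix(rep(c(0.3, -0.1, 0.2), each = 2), 2, 3)
  tr <- run_nve(tp, tp$x_native,
                run_config(temperature = 0, n_steps = 500, stride = 10),
                v0 = v0)
  etot <- tr$e_pot + tr$e_kin
  expect_lt(max(etot) - min(etot), 1e-12)
  expect_lt(max(abs(tr$e_pot)), 1e-12)
})

test_that("NVE energy error scales as dt^2", {
  # the stiffest bond mode caps the stable step near dt ~ 0.014; probe the
  # asymptotic regime below that
  fx <- fx_pierced_C14()
  dts <- c(0.001, 0.002, 0.004)
  errs <- vapply(dts, function(dt0) {
    tr <- run_nve(fx$ox, fx$ox$x_native,
                  run_config(temperature = 0.2, n_steps = round(50 / dt0),
                             dt = dt0, stride = 10, seed = 2))
    etot <- tr$e_pot + tr$e_kin
    max(etot) - min(etot)
  }, numeric(1))
  slope <- coef(lm(log(errs) ~ log(dts)))[2]
  expect_gt(slope, 1.7)
  expect_lt(slope, 2.3)
})

test_that("umbrella runs bias the smooth Q and record the bias exactly", {
  fx <- fx_pierced_C14()
  cfg <- run_config(temperature = 0.9, n_steps = 1e5, stride = 100, seed = 3)
  tr <- run_umbrella(fx$ox, fx$ox$x_native, cfg, q_center = 0.5, k_umb = 60)
  qm <- mean(tr$Q_smooth[-(1:200)])
  expect_gt(qm, 0.35)
  expect_lt(qm, 0.65)
  expect_lt(max(abs(tr$e_bias - 0.5 * 60 * (tr$Q_smooth - 0.5)^2)), 1e-9)

  # k_umb = 0 reduces exactly to the unbiased run
  tr0 <- run_umbrella(fx$ox, fx$ox$x_native,
                      run_config(temperature = 0.8, n_steps = 2000,
                                 stride = 100, seed = 9),
                      q_center = 0.5, k_umb = 0)
  trl <- run_langevin(fx$ox, fx$ox$x_native,
                      run_config(temperature = 0.8, n_steps = 2000,
                                 stride = 100, seed = 9))
  expect_identical(tr0$frames, trl$frames)

  expect_error(run_umbrella(fx$ox, cfg = cfg, k_umb = -1), "non-negative")
  expect_error(run_umbrella(fx$ox, cfg = cfg, q_center = 2), "0, 1")
})

test_that("the extended coil is unfolded and respects covalent closure", {
  fx <- fx_pierced_C14()
  x0 <- extended_coil(fx$ox)
  q0 <- compute_Q(fake_traj(list(x0), fx$ox$n), fx$ox$contact_map)$Q
  expect_lt(q0, 0.05)
  ssd <- sqrt(sum((x0[fx$bridge[1], ] - x0[fx$bridge[2], ])^2))
  expect_lt(ssd, 0.9)    # loop closed (SS bond intact), nm
  e <- sbm_energy(fx$ox, x0)
  expect_lt(e$bond, 500)     # residual closure strain, removed within steps
  expect_lt(e$repulsive, 50)
})

test_that("pathological starts and blow-ups are reported", {
  fx <- fx_pierced_C14()
  expect_error(
    run_langevin(fx$ox, fx$ox$x_native * 0.05,
                 run_config(temperature = 1, n_steps = 100, stride = 10)),
    "clash"
  )
  # coincident contact partners make the energy singular immediately
  pair <- fx$ox$contact_map[1, ]
  coincident <- fx$ox$x_native
  coincident[pair$j, ] <- coincident[pair$i, ]
  expect_error(
    run_nve(fx$ox, coincident,
            run_config(temperature = 0, n_steps = 100, stride = 10)),
    "coincident"
  )
})
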