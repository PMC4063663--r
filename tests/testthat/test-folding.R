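test_that("Q is 1 at the native frame and near 0 for the coil", {
  fx <- fx_pierced_C14()
  tr <- fake_traj(list(fx$ox$x_native, extended_coil(fx$ox)), fx$ox$n)
  q <- compute_Q(tr, fx$ox$contact_map)
  expect_equal(q$Q[1], 1)
  expect_lt(q$Q[2], 0.05)
  expect_error(compute_Q(tr, fx$ox$contact_map[0, ]), "empty")
  expect_error(compute_Q(tr, fx$ox$contact_map, lambda = 0.9), "lambda")
})

test_that("Q agrees with a per-pair brute-force recount", {
  fx <- fx_pierced_C14()
  tr <- run_langevin(fx$ox, fx$ox$x_native,
                     run_config(temperature = 0.9, n_steps = 5000,
                                stride = 500, seed = 3))
  q <- compute_Q(tr, fx$ox$contact_map)$Q
  cm <- fx$ox$contact_map
  for (f in seq_len(nrow(tr$frames))) {
    x <- traj_frame(tr, f)
    formed <- sum(vapply(seq_len(nrow(cm)), function(k) {
      sqrt(sum((x[cm$i[k], ] - x[cm$j[k], ])^2)) < 1.2 * cm$r0[k]
    }, logical(1)))
    expect_equal(q[f], formed / nrow(cm))
  }
})

test_that("q_segment restricts to a segment's contacts", {
  fx <- fx_pierced_C14()
  tr <- fake_traj(list(fx$ox$x_native), fx$ox$n)
  whole <- compute_q_segment(tr, fx$ox$contact_map, c(1, fx$ox$n))
  expect_equal(whole$q_segment, compute_Q(tr, fx$ox$contact_map)$Q)
  loopless <- fx$ox$contact_map[fx$ox$contact_map$i > 5 &
                                  fx$ox$contact_map$j > 5, ]
  expect_error(compute_q_segment(tr, loopless, c(1, 5)),
               "no native contacts")

  # hand-count for the thread helix segment on a perturbed frame
  segs <- attr(fx$s, "segments")
  set.seed(2)
  x <- fx$ox$x_native + matrix(rnorm(3 * fx$ox$n, sd = 0.05), fx$ox$n, 3)
  tr2 <- fake_traj(list(x), fx$ox$n)
  rng <- segs$thread
  qs <- compute_q_segment(tr2, fx$ox$contact_map, rng)
  cm <- fx$ox$contact_map
  own <- (cm$i >= rng[1] & cm$i <= rng[2]) | (cm$j >= rng[1] & cm$j <= rng[2])
  sub <- cm[own, ]
  formed <- sum(vapply(seq_len(nrow(sub)), function(k) {
    sqrt(sum((x[sub$i[k], ] - x[sub$j[k], ])^2)) < 1.2 * sub$r0[k]
  }, logical(1)))
  expect_equal(qs$q_segment, formed / nrow(sub))
  expect_equal(attr(qs, "n_contacts"), nrow(sub))
})

test_that("transition detection finds ramps and telegraphs", {
  ramp <- seq(0, 1, length.out = 200)
  ev <- detect_transitions(ramp, 0.2, 0.8, min_dwell = 10)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "folding")

  telegraph <- rep(rep(c(0.05, 0.95), 5), each = 50)
  ev2 <- detect_transitions(telegraph, 0.2, 0.8, min_dwell = 10)
  expect_equal(sum(ev2$type == "folding"), 5)
  expect_equal(sum(ev2$type == "unfolding"), 4)

  # dwells shorter than min_dwell are ignored
  blip <- c(rep(0.05, 100), rep(0.95, 3), rep(0.05, 100))
  expect_equal(nrow(detect_transitions(blip, 0.2, 0.8, min_dwell = 10)), 0)
})

test_that("WHAM recovers harmonic-oscillator thermodynamics", {
  set.seed(42)
  temps <- c(0.8, 1.0, 1.25)
  es <- lapply(temps, function(T0) 0.5 * T0 * rchisq(20000, df = 1))
  th <- wham_cv(es, temps, n_bins = 200)
  cv1 <- th$cv$Cv[which.min(abs(th$cv$T - 1.0))]
  expect_equal(cv1, 0.5, tolerance = 0.02)
  expect_true(all(th$cv$Cv >= 0))
  expect_equal(th$Tf, th$cv$T[which.max(th$cv$Cv)])

  # permutation invariance
  th2 <- wham_cv(rev(es), rev(temps), n_bins = 200)
  expect_equal(th$Tf, th2$Tf)
  expect_equal(th$cv$Cv, th2$cv$Cv, tolerance = 1e-8)

  # non-overlapping histograms error with the overlap matrix
  expect_error(wham_cv(list(rnorm(100, 0, 0.1), rnorm(100, 50, 0.1)),
                       c(1, 1.1)),
               "overlap")
})

test_that("umbrella WHAM recovers a quadratic free-energy profile", {
  a <- 120; q0 <- 0.5; T0 <- 1.0
  set.seed(7)
  qs <- rnorm(5e4, mean = q0, sd = sqrt(T0 / (2 * a)))
  fq <- wham_fq(list(qs), q_centers = q0, k_umbs = 0, temperature = T0,
                n_bins = 60)
  sel <- fq$count > 100
  fit <- lm(F ~ poly(Q, 2, raw = TRUE), data = fq[sel, ])
  expect_equal(unname(coef(fit)[3]), a, tolerance = 0.05)

  # a biased window unbiases back to the same curvature
  k_u <- 200; qc <- 0.6
  atot <- a + k_u / 2
  mu <- (2 * a * q0 + k_u * qc) / (2 * atot)
  set.seed(8)
  qs2 <- rnorm(5e4, mean = mu, sd = sqrt(T0 / (2 * atot)))
  fq2 <- wham_fq(list(qs2), q_centers = qc, k_umbs = k_u, temperature = T0,
                 n_bins = 60)
  fit2 <- lm(F ~ poly(Q, 2, raw = TRUE), data = fq2[fq2$count > 100, ])
  expect_equal(unname(coef(fit2)[3]), a, tolerance = 0.05)
})

test_that("mechanism curves put the whole chain on the diagonal", {
  fx <- fx_pierced_C14()
  runs <- lapply(1:2, function(k) {
    run_langevin(fx$ox, fx$ox$x_native,
                 run_config(temperature = 0.95, n_steps = 1e5, stride = 100,
                            seed = 20 + k))
  })
  mc <- mechanism_curves(runs, fx$ox$contact_map,
                         list(whole = c(1, fx$ox$n)), n_bins = 10,
                         n_boot = 50)
  filled <- mc[mc$count > 30, ]
  expect_true(all(abs(filled$q_mean - filled$Q_mid) < 0.06))
  expect_equal(sum(mc$count), length(runs[[1]]$Q) * 2)  # bins cover all frames
})
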