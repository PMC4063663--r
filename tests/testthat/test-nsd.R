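test_that("rigid translation leaves no aligned fluctuation", {
  fx <- fx_pierced_C14()
  n <- fx$ox$n
  frames <- lapply(seq_len(10 * n + 5), function(t) {
    fx$ox$x_native + matrix(rep(c(0.01 * t, -0.02 * t, 0.005 * t), each = n),
                            n, 3)
  })
  tr <- fake_traj(frames, n)
  expect_error(pca_fluctuations(tr, n_components = 4), "rank-deficient")
})

test_that("a constructed breathing mode is recovered", {
  fx <- fx_pierced_C14()
  n <- fx$ox$n
  set.seed(21)
  mode <- matrix(rnorm(3 * n), n, 3)
  mode <- mode / sqrt(sum(mode^2))
  noise_amp <- 0.002
  frames <- lapply(seq_len(10 * n + 20), function(t) {
    fx$ox$x_native + 0.15 * sin(0.37 * t) * mode +
      matrix(rnorm(3 * n, sd = noise_amp), n, 3)
  })
  tr <- fake_traj(frames, n)
  prof <- pca_fluctuations(tr, n_components = 4)
  ev <- attr(prof, "eigenvalues")
  expect_true(all(diff(ev) <= 1e-12))        # non-increasing spectrum
  mode_amp <- sqrt(rowSums(mode^2))
  cos_sim <- sum(prof$amplitude * mode_amp) /
    sqrt(sum(prof$amplitude^2) * sum(mode_amp^2))
  expect_gt(cos_sim, 0.99)
})

test_that("profiles are invariant to a global rotation of the trajectory", {
  fx <- fx_pierced_C14()
  n <- fx$ox$n
  set.seed(22)
  frames <- lapply(seq_len(10 * n + 10), function(t) {
    fx$ox$x_native + matrix(rnorm(3 * n, sd = 0.01), n, 3)
  })
  tr <- fake_traj(frames, n)
  R <- random_rotation(5)
  tr_rot <- fake_traj(lapply(frames, function(x) x %*% R), n)
  p1 <- pca_fluctuations(tr, 4)
  p2 <- pca_fluctuations(tr_rot, 4)
  expect_equal(p1$amplitude, p2$amplitude, tolerance = 1e-6)
})

test_that("profile differencing and its guards work", {
  p1 <- structure(tibble::tibble(residue = 1:50, amplitude = runif(50)),
                  class = c("nsd_profile", class(tibble::tibble())))
  d0 <- nsd_difference(p1, p1, c(20, 40))
  expect_true(all(d0$delta == 0))
  expect_true(all(d0$local[10:30 + 10]))
  p2 <- structure(tibble::tibble(residue = 1:40, amplitude = runif(40)),
                  class = class(p1))
  expect_error(nsd_difference(p1, p2, c(20, 40)), "mismatch")
  expect_error(nsd_permutation_test(p1, p1, c(20, 40)), "block")
})

test_that("native-state sampling guards its basin", {
  fx <- fx_pierced_C14()
  expect_error(sample_native(fx$ox, tf = 0.88, t_frac = 1.2), "t_frac")
  # an impossible retention demand exercises the discard guard
  expect_error(
    sample_native(fx$ox, tf = 0.88, t_frac = 0.9, n_steps = 3e4,
                  stride = 30, seed = 2, q_min = 0.999),
    "discarded"
  )
  tr <- sample_native(fx$ox, tf = 0.88, t_frac = 0.6, n_steps = 5e4,
                      stride = 50, seed = 3)
  expect_gt(attr(tr, "retention"), 0.99)
  expect_true(all(tr$Q > 0.85))
})
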