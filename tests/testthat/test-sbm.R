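test_that("contact map matches exhaustive recomputation", {
  fx <- fx_pierced_C14()
  ca <- ca_coords(fx$s)
  dd <- as.matrix(dist(ca))
  brute <- which(upper.tri(dd) & dd < 8 & abs(row(dd) - col(dd)) >= 4,
                 arr.ind = TRUE)
  expect_equal(nrow(fx$cm), nrow(brute))
  expect_equal(fx$cm$r0 * 10, dd[brute[order(brute[, 1], brute[, 2]), ,
                                        drop = FALSE]],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("contact map basics: inclusion, shadow screening, errors", {
  # valid zig-zag chain whose ends sit 7 A apart at |i-j| = 5, with residue 3
  # exactly on the 1-6 segment (screened under the shadow approximation)
  zig <- rbind(c(0, 0, 0), c(1.75, 3.374, 0), c(3.5, 0, 0),
               c(3.5, -3.8, 0), c(7, -3.8, 0), c(7, 0, 0))
  s <- tiny_structure(zig)
  cm <- build_contact_map(s, cutoff = 8, min_seq_sep = 5)
  expect_true(any(cm$i == 1 & cm$j == 6))
  cm_shadow <- build_contact_map(s, method = "shadow_approx", cutoff = 8,
                                 min_seq_sep = 5)
  expect_false(any(cm_shadow$i == 1 & cm_shadow$j == 6))

  expect_error(build_contact_map(s, cutoff = -1), "positive")
})

test_that("oxidation states shape bonds and contacts as specified", {
  fx <- fx_pierced_C14()
  n <- nrow(fx$s)
  dyn <- build_topology(fx$s, fx$cm, fx$bridge, state = "dynamic")
  expect_equal(nrow(fx$ox$bonds), n)              # (n-1) chain + 1 SS bond
  expect_equal(nrow(fx$red$bonds), n - 1)
  ss_was_contact <- any(fx$cm$i == fx$bridge[1] & fx$cm$j == fx$bridge[2])
  expect_true(ss_was_contact)                     # 5.5 A pair is native
  expect_equal(nrow(dyn$contacts), nrow(fx$red$contacts) + 1)
  expect_equal(nrow(fx$ox$contacts), nrow(fx$red$contacts))
  expect_error(build_topology(fx$s, fx$cm, c(5, 6)), "bonded neighbors")

  # dynamic SS contact is anchored at -eps_ss at the native separation
  e_dyn <- sbm_energy(dyn, dyn$x_native)
  e_red <- sbm_energy(fx$red, fx$red$x_native)
  expect_equal(e_dyn$contact, e_red$contact - 1, tolerance = 1e-9)
})

test_that("native energies and closed forms hold", {
  fx <- fx_pierced_C14()
  e <- sbm_energy(fx$ox, fx$ox$x_native)
  expect_equal(e$bond, 0, tolerance = 1e-9)
  expect_equal(e$angle, 0, tolerance = 1e-9)
  expect_equal(e$dihedral, 0, tolerance = 1e-9)
  expect_equal(e$contact, -nrow(fx$ox$contacts), tolerance = 1e-9)

  # single stretched bond: (k/2) delta^2 exactly
  x <- fx$ox$x_native
  b1 <- x[2, ] - x[1, ]
  delta <- 0.013
  x2 <- x
  x2[1, ] <- x[1, ] - delta * b1 / sqrt(sum(b1^2))
  de <- sbm_energy(fx$ox, x2)$bond - e$bond
  expect_equal(de, 0.5 * 2e4 * delta^2, tolerance = 1e-6)
})

test_that("energy matches an independent term-by-term oracle", {
  fx <- fx_pierced_C14()
  set.seed(30)
  for (rep in 1:8) {
    x <- fx$ox$x_native + matrix(rnorm(3 * fx$ox$n, sd = 0.05), fx$ox$n, 3)
    e <- sbm_energy(fx$ox, x)
    o <- oracle_energy(fx$ox, x)
    for (term in c("bond", "angle", "dihedral", "contact", "repulsive")) {
      expect_equal(e[[term]], o[[term]], tolerance = 1e-8)
    }
  }
})

test_that("energy is invariant under rigid-body transforms", {
  fx <- fx_pierced_C14()
  set.seed(8)
  x <- fx$ox$x_native + matrix(rnorm(3 * fx$ox$n, sd = 0.03), fx$ox$n, 3)
  R <- random_rotation(12)
  x2 <- x %*% R
  x2 <- sweep(x2, 2, c(1.3, -0.2, 5))
  expect_equal(sbm_energy(fx$ox, x)$total, sbm_energy(fx$ox, x2)$total,
               tolerance = 1e-9)
})

test_that("contact term is bounded below by -eps per contact", {
  fx <- fx_pierced_C14()
  set.seed(9)
  for (rep in 1:10) {
    x <- fx$ox$x_native + matrix(rnorm(3 * fx$ox$n, sd = runif(1, 0, 0.5)),
                                 fx$ox$n, 3)
    expect_gte(sbm_energy(fx$ox, x)$contact, -nrow(fx$ox$contacts))
  }
})

test_that("forces are the analytic gradient with zero net force and torque", {
  fx <- fx_pierced_C14()
  set.seed(31)
  h <- 1e-6
  for (rep in 1:4) {
    x <- fx$ox$x_native + matrix(rnorm(3 * fx$ox$n, sd = 0.03), fx$ox$n, 3)
    f <- sbm_forces(fx$ox, x)
    expect_lt(max(abs(colSums(f))), 1e-8)                 # net force
    torque <- colSums(cbind(
      x[, 2] * f[, 3] - x[, 3] * f[, 2],
      x[, 3] * f[, 1] - x[, 1] * f[, 3],
      x[, 1] * f[, 2] - x[, 2] * f[, 1]
    ))
    expect_lt(max(abs(torque)), 1e-6)                     # net torque
    for (kk in sample(seq_len(3 * fx$ox$n), 8)) {
      i <- (kk - 1) %/% 3 + 1
      c0 <- (kk - 1) %% 3 + 1
      xp <- x; xp[i, c0] <- xp[i, c0] + h
      xm <- x; xm[i, c0] <- xm[i, c0] - h
      fd <- -(sbm_energy(fx$ox, xp)$total - sbm_energy(fx$ox, xm)$total) /
        (2 * h)
      expect_equal(f[i, c0], fd, tolerance = 1e-6 * max(1, abs(fd)))
    }
  }
})

test_that("topology serializes to a readable sectioned text file", {
  fx <- fx_pierced_C14()
  f <- withr::local_tempfile(fileext = ".top")
  write_topology(fx$ox, f)
  txt <- readLines(f)
  expect_true(any(grepl("^\\[bonds\\]", txt)))
  expect_true(any(grepl("^\\[contacts\\]", txt)))
  expect_true(any(grepl("ss_pair", txt)))
})
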