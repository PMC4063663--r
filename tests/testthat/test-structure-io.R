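test_that("a hand-written PDB reads back bit-exactly", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00",
    "ATOM      2  CA  GLY A   2       4.500   2.000   3.000  1.00  0.00",
    "ATOM      3  CA  CYS A   3       6.000   4.000   4.500  1.00  0.00",
    "ATOM      4  SG  CYS A   3       6.500   5.000   5.500  1.00  0.00",
    "END"
  )
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- read_structure(f, chain = "A")
  expect_equal(nrow(s), 3)
  expect_equal(s$aa, c("A", "G", "C"))
  expect_equal(unname(ca_coords(s)[1, ]), c(1, 2, 3))
  expect_equal(unname(ca_coords(s)[3, ]), c(6, 4, 4.5))
  expect_equal(c(s$sgx[3], s$sgy[3], s$sgz[3]), c(6.5, 5, 5.5))
})

test_that("write/read round-trip preserves coordinates and sequence", {
  set.seed(20)
  kinds <- rep(plasso:::bundle_kinds[-1], length.out = 10)
  for (k in seq_along(kinds)) {
    s <- make_bundle(kinds[k], helix_length = 15, seed = 100 + k,
                     jitter = 0.05)
    f <- withr::local_tempfile(fileext = ".pdb")
    write_structure(s, f)
    s2 <- read_structure(f, chain = "A")
    expect_lt(max(abs(ca_coords(s) - ca_coords(s2))), 1e-3)
    expect_identical(s$aa, s2$aa)
    expect_identical(s$resid, s2$resid)
  }
})

test_that("io errors are explicit", {
  s <- make_bundle("cinch", helix_length = 14)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  expect_error(read_structure(f, chain = "Z"), "available chains")
  expect_error(write_structure(s[0, ], tempfile()), "empty")
})

test_that("disulphide detection pairs nearest cysteines once each", {
  s <- make_bundle("none", helix_length = 14)
  expect_equal(nrow(detect_disulphides(s)), 0)

  s2 <- make_bundle("cinch", helix_length = 14)
  br <- detect_disulphides(s2)
  expect_equal(nrow(br), 1)
  expect_equal(c(br$i, br$j), as.integer(attr(s2, "cys_pair")))
  expect_equal(br$method, "sg")
  expect_lt(br$distance, 2.5)

  # four cysteines forming two spatially separated pairs, Calpha fallback:
  # compare with exhaustive minimum-weight pairing
  set.seed(5)
  ca <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 0, 30), c(5.5, 0, 30),
              c(20, 0, 15), c(40, 0, 15))
  # reorder so pairs are not adjacent
  ord <- c(1, 5, 3, 6, 2, 4)
  s4 <- tiny_structure(ca[ord, ], aa = c("C", "A", "C", "A", "C", "C"))
  br4 <- detect_disulphides(s4, ca_cutoff = 7)
  perms <- list(c(1, 3, 5, 6), c(1, 5, 3, 6), c(1, 6, 3, 5))
  cys <- which(s4$aa == "C")
  d <- as.matrix(dist(ca_coords(s4)))
  best <- NULL
  for (p in list(rbind(cys[c(1, 2)], cys[c(3, 4)]),
                 rbind(cys[c(1, 3)], cys[c(2, 4)]),
                 rbind(cys[c(1, 4)], cys[c(2, 3)]))) {
    w <- d[p[1, 1], p[1, 2]] + d[p[2, 1], p[2, 2]]
    if (is.null(best) || w < best$w) best <- list(w = w, p = p)
  }
  got <- apply(as.matrix(br4[, c("i", "j")]), 1, function(r) {
    paste(sort(r), collapse = "-")
  })
  want <- apply(best$p, 1, function(r) paste(sort(r), collapse = "-"))
  expect_setequal(got, want)
})

test_that("detection is invariant under rigid-body transforms", {
  s <- make_bundle("cinch", helix_length = 14)
  R <- random_rotation(3)
  ca <- ca_coords(s) %*% R + 5   # uniform shift
  sg <- cbind(s$sgx, s$sgy, s$sgz) %*% R + 5
  s2 <- new_structure(s$resid, s$aa, ca, sg)
  expect_equal(detect_disulphides(s)[, c("i", "j")],
               detect_disulphides(s2)[, c("i", "j")])
})

test_that("chain breaks and virtual bonds are validated", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(30, 0, 0))
  expect_error(validate_structure(tiny_structure(ca)), "virtual bond")
  s_gap <- tiny_structure(ca, resid = c(1L, 2L, 3L, 9L))
  expect_silent(validate_structure(s_gap))   # numbering gap, not a bond error
  br <- chain_breaks(s_gap)
  expect_equal(br$after, 3L)
  expect_error(new_structure(c(1, 3, 2), rep("A", 3), ca[1:3, ]),
               "strictly increasing")
})
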