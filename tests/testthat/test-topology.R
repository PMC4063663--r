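test_that("close_loop yields the covalent loop polyline", {
  s <- make_bundle("cinch", helix_length = 28, cys_pair = c(96, 146))
  curve <- close_loop(s, c(96, 146))
  expect_equal(nrow(curve), 51)     # residues 96..146 inclusive
  expect_equal(attr(curve, "bridge"), c(96, 146))

  tri <- close_loop(s, c(10, 12))
  expect_equal(nrow(tri), 3)
})

test_that("smoothing preserves closure and shortens the curve", {
  set.seed(4)
  closed_len <- function(m) {
    sum(sqrt(rowSums((m[c(2:nrow(m), 1), ] - m)^2)))
  }
  for (rep in 1:25) {
    kind <- sample(c("cinch", "lasso_C", "pierced_C"), 1)
    s <- make_bundle(kind, helix_length = 14, seed = rep, jitter = 0.05)
    cl <- classify_lasso(s)
    prev <- close_loop(s, c(cl$i, cl$j), smooth = 0)
    for (sm in 1:3) {
      cur <- close_loop(s, c(cl$i, cl$j), smooth = sm)
      expect_equal(nrow(cur), nrow(prev) * 2)
      expect_lte(closed_len(cur), closed_len(prev) + 1e-9)
      prev <- cur
    }
  }
})

test_that("close_loop refuses a chain break inside the loop", {
  ca <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 0),
              c(0, 7.6, 0), c(3.8, 7.6, 0))
  s <- tiny_structure(ca, resid = c(1L, 2L, 3L, 7L, 8L, 9L))
  expect_error(close_loop(s, c(2, 6)), "chain break")
  expect_silent(close_loop(s, c(4, 6)))
})

test_that("span_surface triangulates from the centroid", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  surf <- span_surface(sq)
  expect_equal(nrow(surf), 4)
  expect_equal(attr(surf, "area"), 1)
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(attr(span_surface(tri), "area"), 0.5)
  line <- cbind(seq_len(4), 0, 0)
  expect_error(span_surface(line), "degenerate")
})

test_that("count_crossings matches hand geometry on a unit square", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  up <- rbind(c(0.5, 0.5, -1), c(0.5, 0.5, 1))
  cr <- count_crossings(sq, up)
  expect_equal(nrow(cr), 1)
  expect_equal(cr$sign, 1)       # along the fan orientation
  down <- up[2:1, ]
  expect_equal(count_crossings(sq, down)$sign, -1)
  outside <- rbind(c(5, 5, -1), c(5, 5, 1))
  expect_equal(nrow(count_crossings(sq, outside)), 0)
})

test_that("net crossings agree with the brute-force oracle on random instances", {
  set.seed(99)
  n_agree <- 0
  for (rep in 1:200) {
    m <- sample(4:9, 1)
    curve <- matrix(rnorm(3 * m, sd = 2), m, 3)
    chain <- matrix(rnorm(9, sd = 3), 3, 3)
    net_pkg <- sum(count_crossings(curve, chain)$sign)
    net_orc <- oracle_net_crossings(curve, jitter_chain(chain))
    expect_equal(net_pkg, net_orc)
    n_agree <- n_agree + (net_pkg == net_orc)
  }
  expect_equal(n_agree, 200)
})

test_that("net crossings are invariant under rigid transforms and smoothing", {
  for (kind in c("pierced_C", "pierced_N", "lasso_C")) {
    s <- make_bundle(kind, helix_length = 14)
    cl0 <- classify_lasso(s, smooth = 2)
    R <- random_rotation(17)
    shift <- c(10, -4, 2)
    ca <- sweep(ca_coords(s) %*% R, 2, shift, `+`)
    sg <- sweep(cbind(s$sgx, s$sgy, s$sgz) %*% R, 2, shift, `+`)
    s2 <- new_structure(s$resid, s$aa, ca, sg)
    cl1 <- classify_lasso(s2, smooth = 2)
    expect_equal(c(cl1$net_N, cl1$net_C), c(cl0$net_N, cl0$net_C))
    expect_false(cl0$ambiguous)   # same answer across smoothing rounds 0-3
  }
})

test_that("the leptin-analog bridge gives a 50-residue C-terminal lasso", {
  s <- make_bundle("cinch", helix_length = 28, cys_pair = c(96, 146))
  cl <- classify_lasso(s, c(96, 146))
  expect_equal(cl$loop_size, 50)
  expect_equal(cl$resid_i, 96L)
  expect_equal(cl$resid_j, 146L)
  expect_equal(cl$terminus, "C")
})

test_that("scan_candidates applies the loop-size window and reports reasons", {
  structures <- list(
    small = make_bundle("pierced_C", helix_length = 12),   # loop 32
    mid = make_bundle("pierced_N", helix_length = 18,
                      spacer_length = 12, thread_length = 12),  # loop 45
    large = make_bundle("pierced_N", helix_length = 30,
                        spacer_length = 14, thread_length = 12), # loop 68
    empty = make_bundle("lasso_C", helix_length = 18)
  )
  rep <- scan_candidates(structures, loop_min = 40, loop_max = 200)
  expect_setequal(rep$structure_id[rep$keep], c("mid", "large"))
  expect_match(rep$reason[rep$structure_id == "small"], "too small")
  expect_match(rep$reason[rep$structure_id == "empty"], "not pierced")
  expect_equal(nrow(scan_candidates(list())), 0)
})
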