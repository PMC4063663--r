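#' @title Idealized four-helix bundle generators
#' @description
#' Synthetic up-up-down-down four-helix bundles with configurable cysteine
#' placement, emulating the covalent-loop taxonomy of helical cytokines:
#' zero knot, cinch, empty loop, N-/C-terminal lasso, and pierced (threaded)
#' variants. Helices use ideal Calpha geometry (rise 1.5 A/residue, radius
#' 2.3 A, 100 degrees/residue); connecting loops are smooth spline
#' interpolations resampled at virtual-bond spacing. Pierced kinds use a
#' helical-hairpin lasso whose aperture is pierced perpendicular to the loop
#' plane by a thread helix, which guarantees a clean single crossing by
#' construction.
#' @name bundle
NULL

helix_rise <- 1.5
helix_radius <- 2.3
helix_turn <- 100 * pi / 180

# ideal helix Calpha trace along an arbitrary axis
helix_points <- function(n, base, axis, phase = 0) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(
    axis[2] * u[3] - axis[3] * u[2],
    axis[3] * u[1] - axis[1] * u[3],
    axis[1] * u[2] - axis[2] * u[1]
  )
  k <- seq_len(n) - 1
  ang <- phase + k * helix_turn
  t(vapply(seq_len(n), function(i) {
    base + axis * helix_rise * k[i] +
      helix_radius * (cos(ang[i]) * u + sin(ang[i]) * v)
  }, numeric(3)))
}

# Catmull-Rom spline through control points, resampled to m interior points
# at (approximately) uniform arclength between fixed endpoints p0 and p1.
# t0/t1 are the chain directions leaving p0 and entering p1; short lead
# waypoints along them keep the path clear of the helix bodies.
connector_points <- function(p0, p1, waypoints = NULL, spacing = 3.5,
                             n_min = 2, t0 = NULL, t1 = NULL, lead = 3) {
  lead_out <- if (is.null(t0)) NULL else p0 + lead * t0 / sqrt(sum(t0^2))
  lead_in <- if (is.null(t1)) NULL else p1 - lead * t1 / sqrt(sum(t1^2))
  ctrl <- rbind(p0, lead_out, do.call(rbind, waypoints), lead_in, p1)
  # pad ends for Catmull-Rom tangents
  ctrl <- rbind(2 * ctrl[1, ] - ctrl[2, ], ctrl,
                2 * ctrl[nrow(ctrl), ] - ctrl[nrow(ctrl) - 1, ])
  # centripetal Catmull-Rom (Barry-Goldman): no overshoot loops when
  # control points are unevenly spaced
  cr_segment <- function(P, n_eval = 40) {
    tk <- c(0, cumsum(sqrt(sqrt(rowSums(diff(P)^2)) + 1e-9)))
    tt <- seq(tk[2], tk[3], length.out = n_eval)
    t(vapply(tt, function(u) {
      A1 <- (tk[2] - u) / (tk[2] - tk[1]) * P[1, ] + (u - tk[1]) / (tk[2] - tk[1]) * P[2, ]
      A2 <- (tk[3] - u) / (tk[3] - tk[2]) * P[2, ] + (u - tk[2]) / (tk[3] - tk[2]) * P[3, ]
      A3 <- (tk[4] - u) / (tk[4] - tk[3]) * P[3, ] + (u - tk[3]) / (tk[4] - tk[3]) * P[4, ]
      B1 <- (tk[3] - u) / (tk[3] - tk[1]) * A1 + (u - tk[1]) / (tk[3] - tk[1]) * A2
      B2 <- (tk[4] - u) / (tk[4] - tk[2]) * A2 + (u - tk[2]) / (tk[4] - tk[2]) * A3
      (tk[3] - u) / (tk[3] - tk[2]) * B1 + (u - tk[2]) / (tk[3] - tk[2]) * B2
    }, numeric(3)))
  }
  dense <- list()
  for (s in seq_len(nrow(ctrl) - 3)) {
    seg <- cr_segment(ctrl[s:(s + 3), ])
    dense[[s]] <- if (s == 1) seg else seg[-1, , drop = FALSE]
  }
  dense <- do.call(rbind, dense)
  seglen <- sqrt(rowSums(diff(dense)^2))
  arclen <- c(0, cumsum(seglen))
  total <- arclen[length(arclen)]
  sample_m <- function(m) {
    targets <- seq(0, total, length.out = m + 2)[2:(m + 1)]
    t(vapply(targets, function(a) {
      i <- findInterval(a, arclen, rightmost.closed = TRUE)
      w <- (a - arclen[i]) / max(arclen[i + 1] - arclen[i], 1e-12)
      dense[i, ] * (1 - w) + dense[i + 1, ] * w
    }, numeric(3)))
  }
  # pick the interior point count whose chords (endpoints included) stay
  # inside the virtual-bond range; chord and arc spacing differ on curved
  # paths, so search near the arclength estimate
  m0 <- max(n_min, round(total / spacing) - 1)
  best <- NULL
  best_pen <- Inf
  for (m in unique(c(pmax(1, (m0 - 4):(m0 + 6)), 1:3))) {
    pts <- sample_m(m)
    chords <- sqrt(rowSums(diff(rbind(p0, pts, p1))^2))
    pen <- sum(pmax(0, chords - 4.4)) + sum(pmax(0, 2.9 - chords))
    if (pen < best_pen) {
      best <- pts
      best_pen <- pen
    }
    if (pen == 0) break
  }
  best
}

bundle_kinds <- c("none", "zero_knot", "cinch", "empty_loop",
                  "lasso_N", "lasso_C", "pierced_N", "pierced_C")

#' Generate an idealized four-helix bundle
#'
#' @param kind one of `"none"`, `"zero_knot"`, `"cinch"`, `"empty_loop"`,
#'   `"lasso_N"`, `"lasso_C"`, `"pierced_N"`, `"pierced_C"`.
#' @param helix_length residues per canonical helix (pierced kinds require
#'   at least 12 so the lasso aperture can admit the thread).
#' @param loop_length minimum residues per connecting loop; loops are extended
#'   automatically when the geometry needs more points to keep virtual bonds
#'   in range.
#' @param cys_pair optional explicit internal residue pair overriding the
#'   kind's default cysteine placement (not allowed for pierced kinds, whose
#'   geometry fixes the pair).
#' @param seed integer; controls the small coordinate jitter.
#' @param thread_length residues in the thread helix of pierced kinds;
#'   default `max(10, 0.75 * helix_length)`.
#' @param spacer_length residues in the spacer helix between lasso and
#'   thread of `pierced_N`; default `helix_length`.
#' @param jitter standard deviation (Angstrom) of isotropic Gaussian noise
#'   added to all coordinates; 0 gives the exact ideal geometry.
#' @return A [new_structure()] tibble with attributes `lasso_kind`,
#'   `expected_label`, `expected_terminus`, `cys_pair` (internal indices) and
#'   `segments` (residue ranges of the named helices).
#' @export
make_bundle <- function(kind = "pierced_C", helix_length = 18, loop_length = 6,
                        cys_pair = NULL, seed = 1, jitter = 0,
                        thread_length = NULL, spacer_length = NULL) {
  kind <- match.arg(kind, bundle_kinds)
  h <- as.integer(helix_length)
  if (h < 6) stop("helix_length must be at least 6")
  if (kind %in% c("pierced_N", "pierced_C") && h < 12) {
    stop("infeasible geometry: pierced kinds need helix_length >= 12 ",
         "(loop too small to admit the thread)")
  }
  if (kind == "empty_loop" && h < 14) {
    stop("empty_loop needs helix_length >= 14 so the terminal tails stay ",
         "clear of the loop surface")
  }
  if (kind %in% c("pierced_N", "pierced_C") && !is.null(cys_pair)) {
    stop("cys_pair cannot be overridden for pierced kinds")
  }
  H <- helix_rise * (h - 1)
  sp <- 3.5

  segs <- list()   # named list of coordinate blocks
  add <- function(segs, name, pts) { segs[[name]] <- pts; segs }

  if (kind %in% c("none", "zero_knot", "cinch", "empty_loop",
                  "lasso_N", "lasso_C")) {
    d <- 10
    A <- helix_points(h, c(0, 0, 0), c(0, 0, 1))
    B <- helix_points(h, c(d, 0, 0), c(0, 0, 1), phase = pi)
    C <- helix_points(h, c(d, d, H), c(0, 0, -1), phase = pi / 2)
    D <- helix_points(h, c(0, d, H), c(0, 0, -1), phase = 3 * pi / 2)
    up <- c(0, 0, 1); dn <- c(0, 0, -1)
    l1 <- connector_points(A[h, ], B[1, ], list(c(d / 2, -8, H / 2)), sp,
                           loop_length, t0 = up, t1 = up)
    l2 <- connector_points(B[h, ], C[1, ], list(c(d, d / 2, H + 3)), sp,
                           loop_length, t0 = up, t1 = dn)
    l3 <- connector_points(C[h, ], D[1, ], list(c(d / 2, d + 8, H / 2)), sp,
                           loop_length, t0 = dn, t1 = dn)
    segs <- add(segs, "helixA", A); segs <- add(segs, "loop1", l1)
    segs <- add(segs, "helixB", B); segs <- add(segs, "loop2", l2)
    segs <- add(segs, "helixC", C); segs <- add(segs, "loop3", l3)
    segs <- add(segs, "helixD", D)
  } else if (kind == "pierced_C") {
    # lasso ring: post up, arc over, post down, short chain along the
    # aperture bottom so the cysteines meet at a realistic ~5.5 A closure
    w <- 18
    nT <- if (is.null(thread_length)) max(10, round(h * 0.75)) else
      as.integer(thread_length)
    A <- helix_points(h, c(9, -16, 0), c(0, 0, 1))
    Tb <- helix_points(nT, c(9, -8, H / 2), c(0, 1, 0))  # thread helix
    P1 <- helix_points(h, c(0, 0, 0), c(0, 0, 1), phase = 0)         # post C
    P2 <- helix_points(h, c(w, 0, H), c(0, 0, -1), phase = 0)        # post D
    up <- c(0, 0, 1); dn <- c(0, 0, -1); fwd <- c(0, 1, 0)
    arc_w <- lapply(seq(0.25, 0.75, length.out = 3), function(u) {
      c(w * u, 0, H + 4 * sin(pi * u))
    })
    arc <- connector_points(P1[h, ], P2[1, ], arc_w, sp, 4, t0 = up, t1 = dn)
    cys2_pos <- P1[1, ] + c(5.5, 0, 0)
    ringtail <- rbind(
      connector_points(P2[h, ], cys2_pos, list(c(w / 2 + 3, 0, -2)), sp, 2,
                       t0 = dn, t1 = c(-1, 0, 0)),
      cys2_pos
    )
    yend <- Tb[nT, 2]
    l1 <- connector_points(A[h, ], Tb[1, ], list(c(9, -13, H + 2.5)), sp,
                           loop_length, t0 = up, t1 = fwd)
    l2 <- connector_points(Tb[nT, ], P1[1, ],
                           list(c(-6, yend * 0.7, H / 3), c(-6, 2, 0)), sp,
                           loop_length, t0 = fwd, t1 = up)
    segs <- add(segs, "helixA", A); segs <- add(segs, "loop1", l1)
    segs <- add(segs, "thread", Tb); segs <- add(segs, "loop2", l2)
    segs <- add(segs, "postC", P1); segs <- add(segs, "arc", arc)
    segs <- add(segs, "postD", P2); segs <- add(segs, "ringtail", ringtail)
  } else { # pierced_N
    w <- 18
    nT <- if (is.null(thread_length)) max(10, round(h * 0.75)) else
      as.integer(thread_length)
    hC <- if (is.null(spacer_length)) h else as.integer(spacer_length)
    P1 <- helix_points(h, c(0, 0, 0), c(0, 0, 1))                    # post A
    P2 <- helix_points(h, c(w, 0, H), c(0, 0, -1), phase = pi / 3)   # post B
    up <- c(0, 0, 1); dn <- c(0, 0, -1); bwd <- c(0, -1, 0)
    arc_w <- lapply(seq(0.25, 0.75, length.out = 3), function(u) {
      c(w * u, 0, H + 4 * sin(pi * u))
    })
    arc <- connector_points(P1[h, ], P2[1, ], arc_w, sp, 4, t0 = up, t1 = dn)
    cys2_pos <- P1[1, ] + c(5.5, 0, 0)
    ringtail <- rbind(
      connector_points(P2[h, ], cys2_pos, list(c(w / 2 + 3, 0, -2)), sp, 2,
                       t0 = dn, t1 = c(-1, 0, 0)),
      cys2_pos
    )
    C <- helix_points(hC, c(16, 9, 0), c(0, 0, 1), phase = pi)
    Tb <- helix_points(nT, c(9, 10, H / 2), c(0, -1, 0))             # thread
    l2 <- connector_points(cys2_pos, C[1, ], list(c(12, 5, 1)), sp,
                           loop_length, t0 = c(0, 1, 0), t1 = up)
    l3 <- connector_points(C[hC, ], Tb[1, ],
                           list(c(13, 12, max(H / 2 + 4,
                                                1.5 * (hC - 1) + 4))), sp,
                           loop_length, t0 = up, t1 = bwd)
    segs <- add(segs, "postA", P1); segs <- add(segs, "arc", arc)
    segs <- add(segs, "postB", P2); segs <- add(segs, "ringtail", ringtail)
    segs <- add(segs, "loop2", l2)
    segs <- add(segs, "helixC", C); segs <- add(segs, "loop3", l3)
    segs <- add(segs, "thread", Tb)
  }

  ca <- do.call(rbind, unname(segs))
  n <- nrow(ca)
  helix_names <- setdiff(names(segs),
                         c("loop1", "loop2", "loop3", "arc", "ringtail"))
  lens0 <- vapply(segs, nrow, integer(1))
  ends0 <- cumsum(lens0)
  movable <- unlist(lapply(which(!names(segs) %in% helix_names), function(k) {
    (ends0[k] - lens0[k] + 1L):ends0[k]
  }))
  if (jitter > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(seed)
    ca <- ca + matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  ca <- repair_chain(ca, movable)
  lens <- vapply(segs, nrow, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  ranges <- stats::setNames(
    lapply(seq_along(lens), function(k) c(starts[k], ends[k])), names(segs)
  )

  # cysteine pair per kind
  pick_near <- function(range, target) {
    idx <- range[1]:range[2]
    idx[which.min(sqrt(rowSums(sweep(ca[idx, , drop = FALSE], 2, target)^2)))]
  }
  cp <- switch(kind,
    none = NULL,
    zero_knot = c(1L, n),
    cinch = c(ranges$helixB[1], ranges$helixC[2]),
    empty_loop = {
      # large empty loop: internal cysteines on the packed A-D interface,
      # chosen as the closest Calpha pair so the bridge is a realistic
      # contact-distance cross-link (not a long-range tether)
      ai <- (ranges$helixA[1] + 10):ranges$helixA[2]
      di <- ranges$helixD[1]:(ranges$helixD[2] - 10)
      dd <- as.matrix(stats::dist(ca))[ai, di, drop = FALSE]
      k <- arrayInd(which.min(dd), dim(dd))
      c(ai[k[1]], di[k[2]])
    },
    lasso_N = c(2L, pick_near(ranges$loop1, ca[2, ])),
    lasso_C = c(pick_near(ranges$loop3, ca[n - 1, ]), n - 1L),
    pierced_C = c(ranges$postC[1], n),
    pierced_N = c(1L, ranges$ringtail[2])
  )
  if (!is.null(cys_pair)) {
    cp <- sort(as.integer(cys_pair))
    if (cp[1] < 1 || cp[2] > n || diff(cp) < 2) stop("invalid cys_pair")
  }
  if (!is.null(cp)) cp <- sort(cp)

  aa <- rep("A", n)
  sg <- matrix(NA_real_, n, 3)
  if (!is.null(cp)) {
    aa[cp] <- "C"
    m <- (ca[cp[1], ] + ca[cp[2], ]) / 2
    u <- ca[cp[2], ] - ca[cp[1], ]
    u <- u / sqrt(sum(u^2))
    sg[cp[1], ] <- m - 1.025 * u
    sg[cp[2], ] <- m + 1.025 * u
  }

  s <- new_structure(seq_len(n), aa, ca, sg, chain = "A")
  validate_structure(s)
  clash <- min_nonlocal_pair(ca)
  if (clash$d < 3.8) {
    stop("generator produced a clash: residues ", clash$i, " and ", clash$j,
         " at ", round(clash$d, 2), " A")
  }

  expected <- switch(kind,
    none = c(label = "none", terminus = "none"),
    zero_knot = c(label = "zero_knot", terminus = "both-termini"),
    cinch = c(label = "cinch", terminus = "internal"),
    empty_loop = c(label = "cinch", terminus = "internal"),
    lasso_N = c(label = "empty_lasso", terminus = "N"),
    lasso_C = c(label = "empty_lasso", terminus = "C"),
    pierced_N = c(label = "pierced_lasso", terminus = "N"),
    pierced_C = c(label = "pierced_lasso", terminus = "C")
  )
  attr(s, "lasso_kind") <- kind
  attr(s, "expected_label") <- unname(expected["label"])
  attr(s, "expected_terminus") <- unname(expected["terminus"])
  attr(s, "cys_pair") <- cp
  attr(s, "segments") <- ranges
  s
}

# Deterministic relaxation of the connector residues: push apart nonlocal
# pairs closer than the clash floor, restore virtual bonds toward 3.8 A, and
# keep bend angles below angle_cap (a harmonic angle term in theta is
# singular at a straight chain, so near-straight native loop geometry would
# destabilize the dynamics). Helix residues stay pinned at their ideal
# positions.
repair_chain <- function(ca, movable, iters = 1200, clash = 4.5, bond0 = 3.8,
                         angle_cap = 2.6) {
  if (length(movable) == 0) return(ca)
  n <- nrow(ca)
  mov <- rep(FALSE, n)
  mov[movable] <- TRUE
  for (it in seq_len(iters)) {
    grad <- matrix(0, n, 3)
    # bend angles: no triple may be nearly straight; bend at the apex when
    # it is movable, otherwise swing a movable endpoint
    for (k in 2:(n - 1)) {
      if (!mov[k - 1] && !mov[k] && !mov[k + 1]) next
      u <- ca[k - 1, ] - ca[k, ]; v <- ca[k + 1, ] - ca[k, ]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      cth <- sum(u * v) / (nu * nv)
      th <- acos(max(-1, min(1, cth)))
      if (th <= angle_cap) next
      w <- 2 * (th - angle_cap)
      if (mov[k]) {
        mid <- (ca[k - 1, ] + ca[k + 1, ]) / 2
        dir <- ca[k, ] - mid
        dl <- sqrt(sum(dir^2))
        if (dl < 1e-6) {
          ref <- ca[k + 1, ] - ca[k - 1, ]
          dir <- c(-ref[2], ref[1], 0)
          dl <- sqrt(sum(dir^2))
          if (dl < 1e-6) { dir <- c(0, 0, 1); dl <- 1 }
        }
        grad[k, ] <- grad[k, ] - w * dir / dl
      } else {
        # move an endpoint along the in-plane direction that closes the angle
        if (mov[k + 1]) {
          dir <- u / nu - cth * v / nv
          dl <- sqrt(sum(dir^2))
          if (dl > 1e-6) grad[k + 1, ] <- grad[k + 1, ] - w * dir / dl
        } else {
          dir <- v / nv - cth * u / nu
          dl <- sqrt(sum(dir^2))
          if (dl > 1e-6) grad[k - 1, ] <- grad[k - 1, ] - w * dir / dl
        }
      }
    }
    # virtual bonds toward bond0 where out of range
    dvec <- ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE]
    dlen <- sqrt(rowSums(dvec^2))
    for (k in which(dlen < 3.0 | dlen > 4.3)) {
      f <- (dlen[k] - bond0) / dlen[k] * dvec[k, ]
      grad[k, ] <- grad[k, ] - f
      grad[k + 1, ] <- grad[k + 1, ] + f
    }
    # nonlocal clashes
    dd <- as.matrix(stats::dist(ca))
    dd[abs(row(dd) - col(dd)) < 2] <- Inf
    bad <- which(dd < clash & upper.tri(dd), arr.ind = TRUE)
    for (r in seq_len(nrow(bad))) {
      i <- bad[r, 1]; j <- bad[r, 2]
      u <- ca[j, ] - ca[i, ]
      dl <- sqrt(sum(u^2))
      f <- 2 * (clash - dl) / max(dl, 0.5) * u
      # full displacement to the movable partner when the other is pinned
      wi <- if (mov[i] && mov[j]) 0.5 else 1.0
      if (mov[i]) grad[i, ] <- grad[i, ] + wi * f
      if (mov[j]) grad[j, ] <- grad[j, ] - wi * f
    }
    grad[!mov, ] <- 0
    if (max(abs(grad)) < 1e-4) break
    ca <- ca - 0.25 * grad
  }
  ca
}

# closest Calpha pair separated by >= 2 in sequence
min_nonlocal_pair <- function(ca) {
  n <- nrow(ca)
  dd <- as.matrix(stats::dist(ca))
  dd[abs(row(dd) - col(dd)) < 2] <- Inf
  k <- arrayInd(which.min(dd), dim(dd))
  list(i = min(k), j = max(k), d = dd[k])
}

#' Generate a labelled test set of bundles
#'
#' Covers all eight lasso kinds (cycling when `n > 8`), with expected
#' classifications recorded at generation time. Reproducible given `seed`.
#'
#' @param n number of structures.
#' @param seed integer seed (drives per-structure jitter).
#' @param helix_length,loop_length passed to [make_bundle()].
#' @return tibble with columns `kind`, `structure` (list), `expected_label`,
#'   `expected_terminus`, `cys_i`, `cys_j`, `loop_size`.
#' @export
make_test_set <- function(n = 8, seed = 1, helix_length = 18, loop_length = 6) {
  kinds <- rep(bundle_kinds, length.out = n)
  purrr::map_dfr(seq_len(n), function(k) {
    s <- make_bundle(kinds[k], helix_length = helix_length,
                     loop_length = loop_length, seed = seed + k,
                     jitter = 0.05)
    cp <- attr(s, "cys_pair")
    tibble::tibble(
      kind = kinds[k],
      structure = list(s),
      expected_label = attr(s, "expected_label"),
      expected_terminus = attr(s, "expected_terminus"),
      cys_i = if (is.null(cp)) NA_integer_ else cp[1],
      cys_j = if (is.null(cp)) NA_integer_ else cp[2],
      loop_size = if (is.null(cp)) NA_integer_ else cp[2] - cp[1]
    )
  })
}
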