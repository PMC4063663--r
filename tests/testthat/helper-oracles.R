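# Independent brute-force oracles and shared (memoised) expensive fixtures.

# ---- memoisation across test files ----------------------------------------
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# ---- geometric oracle: all-pairs signed segment-triangle intersections ----
# Independent of the package kernel: plain R, solves the 3x3 linear system
# for each (segment, triangle) pair and sums orientation signs.
oracle_net_crossings <- function(curve, chain, smooth = 0) {
  if (smooth > 0) {
    for (r in seq_len(smooth)) {
      n <- nrow(curve)
      nxt <- curve[c(2:n, 1), , drop = FALSE]
      curve <- rbind(0.75 * curve + 0.25 * nxt, 0.25 * curve + 0.75 * nxt)
      idx <- as.vector(t(matrix(seq_len(2 * n), n, 2)))
      curve <- curve[idx, , drop = FALSE]
    }
  }
  n <- nrow(curve)
  cen <- colMeans(curve)
  net <- 0L
  for (s in seq_len(nrow(chain) - 1)) {
    o <- chain[s, ]
    d <- chain[s + 1, ] - o
    hits <- list()
    for (k in seq_len(n)) {
      v0 <- curve[k, ]
      v1 <- curve[if (k == n) 1 else k + 1, ]
      # o + t d = v0 + u (v1-v0) + v (cen-v0)
      A <- cbind(-d, v1 - v0, cen - v0)
      dt <- det(A)
      if (abs(dt) < 1e-14) next
      sol <- solve(A, o - v0)
      t0 <- sol[1]; u <- sol[2]; v <- sol[3]
      if (t0 >= 0 && t0 < 1 && u >= 0 && v >= 0 && u + v <= 1) {
        sgn <- if (det(cbind(v1 - v0, cen - v0, d)) > 0) 1L else -1L
        p <- o + t0 * d
        dup <- any(vapply(hits, function(hh) {
          hh$sgn == sgn && sqrt(sum((hh$p - p)^2)) < 1e-6
        }, logical(1)))
        if (!dup) hits[[length(hits) + 1]] <- list(sgn = sgn, p = p)
      }
    }
    for (hh in hits) net <- net + hh$sgn
  }
  net
}

# deterministic jitter identical to the package's convention
jitter_chain <- function(chain, amp = 1e-6) {
  idx <- seq_len(nrow(chain))
  chain + amp * cbind(sin(137 * idx), cos(41 * idx), sin(89 * idx))
}

# ---- energy oracle: term-by-term recomputation in plain R -----------------
oracle_energy <- function(topology, x) {
  tp <- unclass(topology)
  n <- tp$n
  eb <- 0
  for (r in seq_len(nrow(tp$bonds))) {
    i <- tp$bonds[r, 1]; j <- tp$bonds[r, 2]
    d <- sqrt(sum((x[i, ] - x[j, ])^2))
    eb <- eb + 0.5 * tp$bonds[r, 4] * (d - tp$bonds[r, 3])^2
  }
  ea <- 0
  for (r in seq_len(nrow(tp$angles))) {
    i <- tp$angles[r, 1]; j <- tp$angles[r, 2]; k <- tp$angles[r, 3]
    u <- x[i, ] - x[j, ]; v <- x[k, ] - x[j, ]
    th <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    ea <- ea + 0.5 * tp$angles[r, 5] * (th - tp$angles[r, 4])^2
  }
  cross3 <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
  ed <- 0
  for (r in seq_len(nrow(tp$dihedrals))) {
    i <- tp$dihedrals[r, 1]; j <- tp$dihedrals[r, 2]
    k <- tp$dihedrals[r, 3]; l <- tp$dihedrals[r, 4]
    b1 <- x[j, ] - x[i, ]; b2 <- x[k, ] - x[j, ]; b3 <- x[l, ] - x[k, ]
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
    phi <- atan2(sum(m1 * n2), sum(n1 * n2))
    dphi <- phi - tp$dihedrals[r, 5]
    ed <- ed + tp$dihedrals[r, 6] * (1 - cos(dphi)) +
      tp$dihedrals[r, 7] * (1 - cos(3 * dphi))
  }
  ec <- 0
  for (r in seq_len(nrow(tp$contacts))) {
    i <- tp$contacts[r, 1]; j <- tp$contacts[r, 2]
    rr <- sqrt(sum((x[i, ] - x[j, ])^2))
    G <- exp(-(rr - tp$contacts[r, 3])^2 / (2 * tp$contacts[r, 5]^2))
    ec <- ec + tp$contacts[r, 4] *
      ((1 + (tp$sigma / rr)^12) * (1 - G) - 1)
  }
  er <- 0
  excl <- paste(tp$rep_excl[, 1], tp$rep_excl[, 2])
  shift <- (tp$sigma / tp$rcut)^12
  for (i in seq_len(n - tp$min_rep_sep)) {
    for (j in (i + tp$min_rep_sep):n) {
      if (paste(i, j) %in% excl) next
      rr <- sqrt(sum((x[i, ] - x[j, ])^2))
      if (rr >= tp$rcut) next
      er <- er + tp$eps_rep *
        ((tp$sigma / rr)^12 - shift + 12 * shift * (rr - tp$rcut) / tp$rcut)
    }
  }
  c(bond = eb, angle = ea, dihedral = ed, contact = ec, repulsive = er,
    total = eb + ea + ed + ec + er)
}

# ---- small structure builders ---------------------------------------------
tiny_structure <- function(coords, aa = NULL, resid = NULL) {
  n <- nrow(coords)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(resid)) resid <- seq_len(n)
  new_structure(resid, aa, coords)
}

random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9), 3, 3)
  qr.Q(qr(m)) * sign(det(qr.Q(qr(m))))
}

# a minimal trajectory object for analysis-only tests
fake_traj <- function(frames_list, n, temperature = 1) {
  fm <- do.call(rbind, lapply(frames_list, function(x) as.numeric(t(x))))
  structure(list(
    frames = fm, times = seq_len(nrow(fm)),
    e_pot = numeric(nrow(fm)), e_kin = numeric(nrow(fm)),
    Q = numeric(nrow(fm)), Q_smooth = numeric(nrow(fm)),
    e_bias = numeric(nrow(fm)),
    x_final = frames_list[[length(frames_list)]],
    v_final = NULL, n = n, temperature = temperature,
    dt = 0.005, stride = 1, seed = 1, bias = NULL, mode = "synthetic"
  ), class = "plasso_traj")
}

# ---- shared expensive fixtures --------------------------------------------
fx_pierced_C14 <- function() {
  cached("pierced_C14", {
    s <- make_bundle("pierced_C", helix_length = 14, loop_length = 5)
    cm <- build_contact_map(s)
    list(s = s, cm = cm, bridge = attr(s, "cys_pair"),
         ox = build_topology(s, cm, attr(s, "cys_pair"), state = "oxidized"),
         red = build_topology(s, cm, attr(s, "cys_pair"), state = "reduced"))
  })
}

fx_pierced_N18 <- function() {
  cached("pierced_N18", {
    s <- make_bundle("pierced_N", helix_length = 18, loop_length = 5,
                     spacer_length = 12, thread_length = 12)
    cm <- build_contact_map(s)
    list(s = s, cm = cm, bridge = attr(s, "cys_pair"),
         ox = build_topology(s, cm, attr(s, "cys_pair"), state = "oxidized"),
         red = build_topology(s, cm, attr(s, "cys_pair"), state = "reduced"))
  })
}

# temperature-ladder equilibrium runs + WHAM, both oxidation states
ladder_runs <- function(fx, temps, n_steps, seed0) {
  out <- list()
  for (st in c("ox", "red")) {
    tp <- fx[[st]]
    runs <- lapply(seq_along(temps), function(k) {
      run_langevin(tp, tp$x_native,
                   run_config(temperature = temps[k], n_steps = n_steps,
                              stride = 200, seed = seed0 + k))
    })
    burn <- floor(length(runs[[1]]$Q) * 0.1)
    th <- wham_cv(lapply(runs, function(r) r$e_pot[-seq_len(burn)]), temps)
    out[[st]] <- list(runs = runs, thermo = th)
  }
  out
}

fx_ladder_N18 <- function() {
  cached("ladder_N18", {
    ladder_runs(fx_pierced_N18(), c(0.75, 0.85, 0.9, 0.95), 3e5, 800)
  })
}
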