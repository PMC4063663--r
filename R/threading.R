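#' @title Threading mechanism: slipknot versus plug
#' @description
#' A closed covalent loop can be threaded in two ways: slipknotting, where a
#' hairpin (doubled chain) passes through while the terminus stays on the
#' near side, or plugging, where the free terminus itself passes through.
#' These functions monitor the residues crossing the instantaneous loop
#' surface along a trajectory and classify each folding transition.
#' @name threading-mechanism
NULL

#' Per-frame crossing state of the chain tails through the covalent loop
#'
#' The loop surface is recomputed every analyzed frame from the
#' instantaneous loop coordinates (a native surface is meaningless
#' mid-folding) with a fixed number of corner-cutting rounds. For each tail
#' (walked from the loop attachment outward) the net signed crossing count,
#' the oriented-plane side of the terminal residue and of the tail centroid
#' are recorded. Frames whose loop has collapsed below `area_min` are marked
#' degenerate and excluded from classification windows.
#'
#' @param traj a `plasso_traj` (frames in nm).
#' @param bridge internal index pair `c(i, j)` of the loop-closing cysteines.
#' @param frames optional frame subset (indices); default all.
#' @param stride analyze every `stride`-th of those frames.
#' @param smooth corner-cutting rounds for the loop curve.
#' @param area_min minimum loop fan area (nm^2) before a frame is flagged
#'   degenerate.
#' @return tibble: `frame`, `tail` (`"N"`/`"C"`), `net`, `n_cross`,
#'   `term_side`, `tail_mean_side`, `first_pos`, `last_pos` (crossing
#'   positions counted from the loop attachment), `degenerate`.
#' @export
crossing_trace <- function(traj, bridge, frames = NULL, stride = 1,
                           smooth = 2, area_min = 0.1) {
  ij <- bridge_indices(bridge)
  i <- ij[1]; j <- ij[2]
  n <- traj$n
  if (is.null(frames)) frames <- seq_len(nrow(traj$frames))
  frames <- frames[seq(1, length(frames), by = stride)]
  fm <- traj$frames[frames, , drop = FALSE]
  loop_idx <- i:j
  # the two tail bonds adjoining the loop are excluded: a pierce that close
  # to the closure can slide off the chord edge and is not stable threading
  buf <- 2
  tails <- list(N = if (i - buf > 1) seq(i - buf - 1, 1) else integer(),
                C = if (j + buf < n) seq(j + buf + 1, n) else integer())
  purrr::imap_dfr(tails, function(tl, nm) {
    if (length(tl) < 2) return(NULL)
    st <- cpp_crossing_trace(fm, n, as.integer(loop_idx), as.integer(tl),
                             as.integer(smooth), 1e-6, area_min, 1e-7)
    tibble::tibble(
      frame = frames, tail = nm,
      net = st[, "net"], n_cross = st[, "n_cross"],
      term_side = st[, "term_side"], tail_mean_side = st[, "tail_mean_side"],
      first_pos = st[, "first_pos"] + buf, last_pos = st[, "last_pos"] + buf,
      degenerate = st[, "degenerate"] > 0
    )
  })
}

#' Classify one folding transition as slipknot, plug, or none
#'
#' Establishment is the first analyzed frame inside the transition window
#' where the threading tail's net crossing equals the native parity and
#' persists for at least `min_dwell` analyzed frames. The discriminator is
#' where the chain pierces the surface at establishment, measured along the
#' tail from the loop attachment: a plug event begins with the free terminus
#' passing through, so the crossing sits within `plug_margin` residues of
#' the terminus; a slipknot inserts a doubled chain (hairpin) whose
#' crossings stay in the tail interior throughout.
#' Reaching the end of the window with no persistent crossing is `none`
#' (possible when the disulphide is reduced or dynamic during threading).
#'
#' @param trace output of [crossing_trace()] filtered to the threading tail.
#' @param transition one row of [detect_transitions()] (frame indices on the
#'   same frame numbering as `trace`).
#' @param tail_len number of residues in the threading tail.
#' @param min_dwell persistence requirement, analyzed frames (shared with
#'   transition detection).
#' @param native_net target net crossing; default the modal non-zero net in
#'   the last `min_dwell` frames of the window.
#' @param plug_margin residues from the terminus within which a crossing
#'   counts as a terminal pass; default 3.
#' @return one-row tibble: `label`, `start`, `end`, `establish_frame`,
#'   `first_crossing_residue` (crossing position from the attachment),
#'   `dist_from_terminus`, `n_doubled_frames` (frames with a doubled chain
#'   through the loop just before establishment), `degenerate_flag`.
#' @export
classify_transition <- function(trace, transition, tail_len, min_dwell = 20,
                                native_net = NULL, plug_margin = NULL) {
  stopifnot(length(unique(trace$tail)) == 1)
  if (is.null(plug_margin)) plug_margin <- 3
  win <- trace[trace$frame >= transition$start[1] &
                 trace$frame <= transition$end[1], , drop = FALSE]
  rec <- function(label, est = NA_integer_, fcr = NA_integer_,
                  dft = NA_real_, nd = NA_integer_, flag = FALSE) {
    tibble::tibble(label = label, start = transition$start[1],
                   end = transition$end[1], establish_frame = est,
                   first_crossing_residue = fcr, dist_from_terminus = dft,
                   n_doubled_frames = nd, degenerate_flag = flag)
  }
  if (nrow(win) == 0) return(rec("none"))
  if (mean(win$degenerate) > 0.5) return(rec("none", flag = TRUE))
  ok <- win[!win$degenerate, , drop = FALSE]

  if (is.null(native_net)) {
    last_part <- utils::tail(ok, max(min_dwell, 1))
    nets <- last_part$net[last_part$net != 0]
    if (length(nets) == 0) return(rec("none"))
    native_net <- as.numeric(names(sort(table(nets), decreasing = TRUE))[1])
  }

  established <- ok$net == native_net
  run <- rle(established)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  est_run <- which(run$values & run$lengths >= min_dwell)
  if (length(est_run) == 0) return(rec("none"))
  k0 <- starts[est_run[1]]
  est_frame <- ok$frame[k0]

  est_rows <- ok[k0:min(k0 + 2, nrow(ok)), , drop = FALSE]
  pos <- stats::median(est_rows$last_pos, na.rm = TRUE)
  dft <- tail_len - pos
  # plugging means the free end itself passed through: some frame up to
  # establishment shows the crossing within plug_margin of the terminus.
  # A slipknot threads a hairpin whose crossings stay interior.
  upto <- ok[seq_len(min(k0 + 2, nrow(ok))), , drop = FALSE]
  max_pos <- suppressWarnings(max(upto$last_pos, na.rm = TRUE))
  terminal_pass <- is.finite(max_pos) && max_pos >= tail_len - plug_margin
  n_doubled <- sum(upto$n_cross >= 2 &
                     (upto$last_pos - upto$first_pos) >= 4, na.rm = TRUE)
  label <- if (terminal_pass) "plug" else "slipknot"
  rec(label, est_frame, as.integer(ok$first_pos[k0]), dft,
      as.integer(n_doubled))
}

#' Mechanism fractions with Wilson 95% confidence intervals
#'
#' @param records tibble of transition records from [classify_transition()].
#' @return tibble: `label`, `n`, `fraction`, `ci_lo`, `ci_hi`; fractions sum
#'   to one and are invariant to record order.
#' @export
mechanism_stats <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no transition records to summarize")
  }
  n_tot <- nrow(records)
  labs <- c("slipknot", "plug", "none")
  purrr::map_dfr(labs, function(l) {
    k <- sum(records$label == l)
    ci <- wilson_ci(k, n_tot)
    tibble::tibble(label = l, n = k, fraction = k / n_tot,
                   ci_lo = ci[1], ci_hi = ci[2])
  })
}

wilson_ci <- function(k, n, z = 1.96) {
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Run quenched folding simulations and classify each threading event
#'
#' Launches `n_runs` independent Langevin runs from an extended coil at a
#' temperature below Tf, detects the first folding transition of each, and
#' classifies the threading mechanism of every folding transition against
#' the native crossing parity of the structure. Runs that never fold within
#' the allotted steps contribute no records (the `folded` attribute reports
#' the fraction of runs with at least one).
#'
#' @param topology an `sbm_topology` (oxidized or dynamic state so the loop
#'   is closed while threading).
#' @param s the `plasso_structure` the topology was built from.
#' @param bridge internal index pair of the loop.
#' @param n_runs number of independent quench runs.
#' @param temperature quench temperature, epsilon.
#' @param n_steps steps per run.
#' @param stride frame stride.
#' @param seed base seed; run k uses `seed + k`.
#' @param q_lo,q_hi,min_dwell transition detection parameters (frames).
#' @return tibble of transition records (one per folded run) with a `run`
#'   column; attribute `folded` gives the folded fraction.
#' @export
thread_mechanism_ensemble <- function(topology, s, bridge, n_runs = 30,
                                      temperature = 0.85, n_steps = 3e5,
                                      stride = 200, seed = 1,
                                      q_lo = 0.2, q_hi = 0.8, min_dwell = 5) {
  ij <- bridge_indices(bridge)
  native <- classify_lasso(s, ij)
  tail_name <- if (native$net_N != 0) "N" else "C"
  native_net <- if (tail_name == "N") native$net_N else native$net_C
  tail_len <- if (tail_name == "N") ij[1] - 1 else nrow(s) - ij[2]

  records <- purrr::map_dfr(seq_len(n_runs), function(k) {
    cfg <- run_config(temperature = temperature, n_steps = n_steps,
                      stride = stride, seed = seed + k)
    tr <- run_langevin(topology, extended_coil(topology), cfg)
    ev <- detect_transitions(tr$Q, q_lo, q_hi, min_dwell)
    folds <- which(ev$type == "folding")
    if (length(folds) == 0) return(NULL)
    purrr::map_dfr(seq_along(folds), function(m) {
      e1 <- ev[folds[m], , drop = FALSE]
      # threading may complete after Q first reaches the folded basin: the
      # mechanism window runs to the next unfolding event (or the run end)
      nxt <- ev$start[ev$type == "unfolding" & ev$start > e1$end]
      e1$end <- if (length(nxt) > 0) min(nxt) else length(tr$Q)
      trace <- crossing_trace(tr, ij, frames = e1$start:e1$end)
      trace <- trace[trace$tail == tail_name, , drop = FALSE]
      out <- classify_transition(trace, e1, tail_len = tail_len,
                                 min_dwell = min_dwell,
                                 native_net = native_net)
      out$run <- k
      out
    })
  })
  attr(records, "folded") <- if (n_runs > 0) {
    length(unique(records$run)) / n_runs
  } else NA
  attr(records, "tail") <- tail_name
  records
}
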