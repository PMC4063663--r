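#' @title Folding-coordinate analysis
#' @description
#' The folding transition is monitored by the fraction of native contacts
#' formed, Q (0 = denatured, 1 = native), and the folding mechanism by
#' q_segment, the same fraction restricted to the contacts of one secondary
#' structure element. Plotting mean q_segment against overall Q reveals the
#' average order of events during folding: a segment tracking the diagonal
#' folds in step with the chain, a curve below the diagonal marks a late
#' folder.
#' @name folding-analysis
NULL

#' Fraction of native contacts per frame
#'
#' A contact is formed when its instantaneous separation is below
#' `lambda * r0` (default tolerance factor 1.2).
#'
#' @param traj a `plasso_traj`.
#' @param contacts contact map tibble (`i`, `j`, `r0` in nm).
#' @param lambda tolerance factor (> 1).
#' @return tibble with `frame`, `time`, `Q`.
#' @export
compute_Q <- function(traj, contacts, lambda = 1.2) {
  if (nrow(contacts) == 0) stop("empty contact map")
  if (lambda <= 1) stop("lambda must exceed 1")
  q <- cpp_traj_Q(traj$frames, as.matrix(contacts[, c("i", "j", "r0")]),
                  lambda)
  tibble::tibble(frame = seq_along(q), time = traj$times, Q = q)
}

#' Per-segment fraction of native contacts
#'
#' A contact belongs to a segment when at least one endpoint lies inside it
#' (the ownership convention; both-endpoint ownership would discard the
#' tertiary contacts that make terminal helices late folders).
#'
#' @param traj a `plasso_traj`.
#' @param contacts contact map tibble.
#' @param segment integer range `c(from, to)` of internal residue indices.
#' @param lambda tolerance factor.
#' @return tibble with `frame`, `time`, `q_segment`, and attribute
#'   `n_contacts`.
#' @export
compute_q_segment <- function(traj, contacts, segment, lambda = 1.2) {
  segment <- sort(as.integer(segment[1:2]))
  inside <- (contacts$i >= segment[1] & contacts$i <= segment[2]) |
    (contacts$j >= segment[1] & contacts$j <= segment[2])
  sub <- contacts[inside, , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("segment [", segment[1], ", ", segment[2], "] owns no native contacts")
  }
  q <- cpp_traj_Q(traj$frames, as.matrix(sub[, c("i", "j", "r0")]), lambda)
  out <- tibble::tibble(frame = seq_along(q), time = traj$times, q_segment = q)
  attr(out, "n_contacts") <- nrow(sub)
  out
}

#' Detect folding / unfolding transitions in a Q series
#'
#' Two-state assignment with hysteresis: a frame below `q_lo` is unfolded,
#' above `q_hi` folded, otherwise it keeps the previous state. A transition
#' is a passage between dwells of at least `min_dwell` frames in each basin.
#'
#' @param q numeric vector of per-frame Q, or the tibble from [compute_Q()].
#' @param q_lo,q_hi basin thresholds.
#' @param min_dwell minimum dwell, frames.
#' @return tibble with `type` (`"folding"`/`"unfolding"`), `start` (last
#'   frame in the departing basin), `end` (first frame in the arriving
#'   basin).
#' @export
detect_transitions <- function(q, q_lo = 0.2, q_hi = 0.8, min_dwell = 100) {
  if (is.data.frame(q)) q <- q$Q
  n <- length(q)
  state <- integer(n)   # -1 low, +1 high, 0 undecided carry
  cur <- 0L
  for (k in seq_len(n)) {
    if (q[k] < q_lo) cur <- -1L else if (q[k] > q_hi) cur <- 1L
    state[k] <- cur
  }
  first_decided <- which(state != 0)[1]
  out <- tibble::tibble(type = character(), start = integer(), end = integer())
  if (is.na(first_decided)) return(out)
  runs <- rle(state[first_decided:n])
  ends <- cumsum(runs$lengths) + first_decided - 1L
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$values)[-1]) {
    if (runs$values[k] == runs$values[k - 1]) next
    if (runs$lengths[k] >= min_dwell && runs$lengths[k - 1] >= min_dwell) {
      type <- if (runs$values[k] == 1L) "folding" else "unfolding"
      # start: last frame in the departing basin proper
      dep <- starts[k - 1]:ends[k - 1]
      basin <- if (runs$values[k - 1] == -1L) dep[q[dep] < q_lo] else dep[q[dep] > q_hi]
      s <- if (length(basin) > 0) max(basin) else ends[k - 1]
      out <- dplyr::bind_rows(out, tibble::tibble(type = type, start = s,
                                                  end = starts[k]))
    }
  }
  out
}

#' Mechanism curves: mean q_segment binned by overall Q
#'
#' Pools frames from an ensemble of trajectories, bins them by overall Q,
#' and reports the per-bin mean q_segment for each named segment with
#' bootstrap confidence intervals. The diagonal is the reference: a segment
#' whose curve lies below it at high Q completes late.
#'
#' @param trajs a `plasso_traj` or list of them.
#' @param contacts contact map tibble.
#' @param segments named list of `c(from, to)` residue ranges.
#' @param n_bins number of Q bins on [0, 1].
#' @param lambda tolerance factor.
#' @param n_boot bootstrap replicates for the CI (0 to skip).
#' @param weights optional per-frame weights (e.g. WHAM reweighting to a
#'   common temperature), one vector per trajectory.
#' @return tibble of class `mechanism_curves`: `segment`, `bin`, `Q_mid`,
#'   `q_mean`, `lo`, `hi`, `count`.
#' @export
mechanism_curves <- function(trajs, contacts, segments, n_bins = 20,
                             lambda = 1.2, n_boot = 200, weights = NULL) {
  if (inherits(trajs, "plasso_traj")) trajs <- list(trajs)
  stopifnot(length(segments) > 0, !is.null(names(segments)))
  qa <- unlist(lapply(trajs, function(tr) compute_Q(tr, contacts, lambda)$Q))
  wa <- if (is.null(weights)) rep(1, length(qa)) else unlist(weights)
  stopifnot(length(wa) == length(qa))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(qa, breaks, rightmost.closed = TRUE), 1), n_bins)

  out <- purrr::imap_dfr(segments, function(rng, nm) {
    qs <- unlist(lapply(trajs, function(tr) {
      compute_q_segment(tr, contacts, rng, lambda)$q_segment
    }))
    purrr::map_dfr(seq_len(n_bins), function(b) {
      sel <- which(bin == b)
      if (length(sel) == 0) {
        return(tibble::tibble(segment = nm, bin = b,
                              Q_mid = (breaks[b] + breaks[b + 1]) / 2,
                              q_mean = NA_real_, lo = NA_real_, hi = NA_real_,
                              count = 0L))
      }
      w <- wa[sel]
      m <- sum(w * qs[sel]) / sum(w)
      ci <- c(NA_real_, NA_real_)
      if (n_boot > 0 && length(sel) > 1) {
        boots <- vapply(seq_len(n_boot), function(r) {
          id <- sample(sel, length(sel), replace = TRUE)
          sum(wa[id] * qs[id]) / sum(wa[id])
        }, numeric(1))
        ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
      }
      tibble::tibble(segment = nm, bin = b,
                     Q_mid = (breaks[b] + breaks[b + 1]) / 2,
                     q_mean = m, lo = ci[1], hi = ci[2],
                     count = length(sel))
    })
  })
  class(out) <- c("mechanism_curves", class(out))
  out
}
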