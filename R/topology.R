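#' @title Covalent-loop (pierced lasso) topology classification
#' @description
#' Every disulphide bridge closes a covalent loop. These functions realize the
#' loop as a closed polygonal curve, span it with a centroid-fan surface, and
#' count signed crossings of the chain tails through that surface to decide
#' whether the loop is a zero knot, a cinch, an empty lasso, or a pierced
#' lasso with a threaded segment.
#' @name lasso-topology
NULL

#' Close the covalent loop into a polygonal curve
#'
#' Takes the Calpha polyline of residues `i..j` and closes it with the chord
#' `j -> i` (the disulphide). Optional corner-cutting smoothing (`smooth`
#' rounds) is applied identically wherever curves are used; it preserves
#' closure and shortens the curve.
#'
#' @param s a `plasso_structure`.
#' @param bridge either a row from [detect_disulphides()] or an integer pair
#'   of internal indices `c(i, j)`.
#' @param smooth rounds of corner-cutting (0-3 typical).
#' @return matrix of curve vertices (closed implicitly), with attributes
#'   `bridge` and `smooth`.
#' @export
close_loop <- function(s, bridge, smooth = 0) {
  ij <- bridge_indices(bridge)
  i <- ij[1]; j <- ij[2]
  if (i < 1 || j > nrow(s) || j - i < 2) stop("invalid bridge indices")
  br <- chain_breaks(s)
  inside <- br$after >= i & br$after < j
  if (any(inside)) {
    stop("chain break inside covalent loop (after residue ",
         br$resid_before[which(inside)[1]],
         "); refusing to close a gapped loop")
  }
  curve <- ca_coords(s)[i:j, , drop = FALSE]
  if (smooth > 0) curve <- cpp_chaikin(curve, as.integer(smooth))
  structure(curve, bridge = c(i, j), smooth = smooth)
}

bridge_indices <- function(bridge) {
  if (is.data.frame(bridge)) {
    c(bridge$i[1], bridge$j[1])
  } else {
    sort(as.integer(bridge[1:2]))
  }
}

#' Span a closed curve with a centroid-fan surface
#'
#' Triangulates from the vertex centroid: one triangle per boundary edge, so
#' the fan boundary equals the curve exactly. Net crossing parity through a
#' closed curve is surface-independent, which is why this cheap surface
#' suffices for topology; disagreement across smoothing levels is surfaced as
#' an ambiguity flag by [classify_lasso()] rather than silently resolved.
#'
#' @param curve a closed curve from [close_loop()] (or any n x 3 matrix).
#' @return tibble of triangles with the three vertices unpacked per row, and
#'   attribute `area` (total fan area).
#' @export
span_surface <- function(curve) {
  n <- nrow(curve)
  if (n < 3) stop("need at least 3 vertices to span a surface")
  cen <- colMeans(curve)
  a <- curve
  b <- curve[c(2:n, 1), , drop = FALSE]
  areas <- vapply(seq_len(n), function(k) {
    e1 <- b[k, ] - a[k, ]; e2 <- cen - a[k, ]
    0.5 * sqrt(sum(crossprod3(e1, e2)^2))
  }, numeric(1))
  total <- sum(areas)
  if (total < 1e-6) stop("degenerate (collinear) curve: fan area ~ 0")
  out <- tibble::tibble(
    ax = a[, 1], ay = a[, 2], az = a[, 3],
    bx = b[, 1], by = b[, 2], bz = b[, 3],
    cx = cen[1], cy = cen[2], cz = cen[3],
    area = areas
  )
  attr(out, "area") <- total
  out
}

crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Count signed crossings of a polyline through a loop surface
#'
#' For each chain segment intersecting a fan triangle, one crossing is
#' recorded with sign +1 when the segment runs along the fan orientation and
#' -1 against it. Shared-edge double counts are merged. A fixed deterministic
#' sub-Angstrom jitter is applied to the chain to avoid exact-coplanarity
#' degeneracies; it cannot change a robust crossing.
#'
#' @param curve closed curve (from [close_loop()]); the fan is built
#'   internally so curve and surface stay consistent.
#' @param chain polyline matrix (m x 3) of the tested chain segment(s).
#' @param smooth additional corner-cutting rounds applied to the curve here.
#' @param jitter deterministic perturbation amplitude, Angstrom.
#' @return tibble with one row per crossing: `segment` (1-based index into
#'   `chain`), `sign`, and the intersection point `x`, `y`, `z`.
#' @export
count_crossings <- function(curve, chain, smooth = 0, jitter = 1e-6) {
  if (nrow(chain) < 2) {
    return(tibble::tibble(segment = integer(), sign = integer(),
                          x = numeric(), y = numeric(), z = numeric()))
  }
  idx <- seq_len(nrow(chain))
  chain_j <- chain + jitter * cbind(sin(137 * idx), cos(41 * idx), sin(89 * idx))
  out <- cpp_fan_crossings(curve, chain_j, as.integer(smooth), 1e-6)
  tibble::as_tibble(out)
}

#' Classify the covalent-loop topology of a structure
#'
#' Labels each disulphide bridge as `zero_knot` (both cysteines within
#' `terminal_margin` of their termini), `cinch` (both internal),
#' `empty_lasso` (one terminal cysteine, nothing threaded) or
#' `pierced_lasso` (a tail with nonzero net crossings through the loop
#' surface). Loop size is the sequence separation `j - i`, the convention
#' under which the canonical leptin bridge C96-C146 has a 50-residue lasso.
#'
#' @param s a `plasso_structure`.
#' @param bridge optional bridge (row or index pair); defaults to all bridges
#'   from [detect_disulphides()].
#' @param terminal_margin residues from a terminus within which a cysteine
#'   counts as terminal.
#' @param smooth corner-cutting rounds used for the reported crossings;
#'   ambiguity across rounds 0-3 is flagged.
#' @return tibble with one row per bridge: `label`, `terminus`, `i`, `j`,
#'   `resid_i`, `resid_j`, `loop_size`, `net_N`, `net_C` (net signed
#'   crossings per tail), `threaded_from`, `threaded_to` (internal indices,
#'   `NA` when nothing is threaded) and `ambiguous`.
#' @export
classify_lasso <- function(s, bridge = NULL, terminal_margin = 10, smooth = 2) {
  if (is.null(bridge)) {
    bridges <- detect_disulphides(s)
    if (nrow(bridges) == 0) {
      return(tibble::tibble(
        label = character(), terminus = character(), i = integer(),
        j = integer(), resid_i = integer(), resid_j = integer(),
        loop_size = integer(), net_N = integer(), net_C = integer(),
        threaded_from = integer(), threaded_to = integer(),
        ambiguous = logical()
      ))
    }
    return(purrr::map_dfr(seq_len(nrow(bridges)), function(k) {
      classify_lasso(s, bridges[k, ], terminal_margin, smooth)
    }))
  }

  ij <- bridge_indices(bridge)
  i <- ij[1]; j <- ij[2]
  n <- nrow(s)
  ca <- ca_coords(s)

  tails <- list(
    N = if (i > 1) seq(i - 1, 1) else integer(),   # walk order: loop -> terminus
    C = if (j < n) seq(j + 1, n) else integer()
  )
  levels <- sort(unique(c(0:3, smooth)))
  nets <- list()
  for (sm in levels) {
    curve <- close_loop(s, c(i, j), smooth = sm)
    nets[[as.character(sm)]] <- vapply(tails, function(tl) {
      if (length(tl) < 2) return(0L)
      as.integer(sum(count_crossings(curve, ca[tl, , drop = FALSE])$sign))
    }, integer(1))
  }
  ambiguous <- length(unique(lapply(nets, unname))) > 1
  net <- nets[[as.character(smooth)]]

  is_N_term <- i <= terminal_margin
  is_C_term <- j >= n - terminal_margin + 1
  terminus <- if (is_N_term && is_C_term) "both-termini"
              else if (is_N_term) "N"
              else if (is_C_term) "C"
              else "internal"
  pierced <- any(net != 0)
  label <- if (pierced) "pierced_lasso"
           else if (terminus == "both-termini") "zero_knot"
           else if (terminus == "internal") "cinch"
           else "empty_lasso"

  thr <- c(NA_integer_, NA_integer_)
  if (pierced) {
    tail_name <- names(net)[which(net != 0)[1]]
    thr <- threaded_run(s, c(i, j), tails[[tail_name]], smooth)
  }

  tibble::tibble(
    label = label, terminus = terminus, i = i, j = j,
    resid_i = s$resid[i], resid_j = s$resid[j],
    loop_size = j - i, net_N = net[["N"]], net_C = net[["C"]],
    threaded_from = thr[1], threaded_to = thr[2], ambiguous = ambiguous
  )
}

# Threaded segment: maximal contiguous run of tail residues on the far side
# of the loop surface, adjacent to a crossing. "Far" is the side opposite the
# tail's own majority (the bulk of an unthreaded tail sits in front of the
# loop). The convention is documented rather than asserted against published
# thread lengths, whose measurement rule differs between reports.
threaded_run <- function(s, ij, tail_idx, smooth) {
  if (length(tail_idx) < 2) return(c(NA_integer_, NA_integer_))
  curve <- close_loop(s, ij, smooth = smooth)
  ca <- ca_coords(s)
  chain <- ca[tail_idx, , drop = FALSE]
  cr <- count_crossings(curve, chain)
  if (nrow(cr) == 0) return(c(NA_integer_, NA_integer_))
  # oriented plane side per tail vertex
  nrm <- newell_normal(curve)
  cen <- colMeans(curve)
  side <- sign(as.vector((chain - matrix(cen, nrow(chain), 3, byrow = TRUE)) %*% nrm))
  majority <- sign(sum(side))
  if (majority == 0) majority <- side[1]
  far <- side != majority
  # runs of far-side vertices adjacent to a crossing segment
  cross_at <- sort(unique(cr$segment))   # between walk positions k and k+1
  runs <- split(seq_along(far), cumsum(c(1, diff(far)) != 0))
  best <- NULL
  for (r in runs) {
    if (!all(far[r])) next
    touches <- any(cross_at %in% c(min(r) - 1, max(r)))
    if (touches && (is.null(best) || length(r) > length(best))) best <- r
  }
  if (is.null(best)) return(c(NA_integer_, NA_integer_))
  run_idx <- tail_idx[best]
  c(min(run_idx), max(run_idx))
}

newell_normal <- function(curve) {
  n <- nrow(curve)
  nxt <- curve[c(2:n, 1), , drop = FALSE]
  a <- c(
    sum((curve[, 2] - nxt[, 2]) * (curve[, 3] + nxt[, 3])),
    sum((curve[, 3] - nxt[, 3]) * (curve[, 1] + nxt[, 1])),
    sum((curve[, 1] - nxt[, 1]) * (curve[, 2] + nxt[, 2]))
  ) / 2
  a / max(sqrt(sum(a^2)), 1e-12)
}

#' Filter pierced-lasso candidates by loop size
#'
#' Retains pierced lassos whose loop size lies strictly inside
#' `(loop_min, loop_max)` (defaults 40 and 200, the sequence-separation
#' window used when scanning for threaded candidates). All entries are
#' reported with the reason for rejection, so the filter is auditable.
#'
#' @param structures a list of `plasso_structure` objects (or a single one).
#' @param loop_min,loop_max exclusive loop-size bounds.
#' @param ... passed to [classify_lasso()].
#' @return tibble: one row per (structure, bridge) with the classification
#'   columns plus `structure_id`, `keep` and `reason`.
#' @export
scan_candidates <- function(structures, loop_min = 40, loop_max = 200, ...) {
  if (inherits(structures, "plasso_structure")) structures <- list(structures)
  out <- purrr::imap_dfr(structures, function(s, id) {
    cl <- classify_lasso(s, ...)
    if (nrow(cl) == 0) return(NULL)
    cl$structure_id <- if (is.character(id)) id else as.character(id)
    cl
  })
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(
      structure_id = character(), label = character(), loop_size = integer(),
      keep = logical(), reason = character()
    ))
  }
  out$keep <- out$label == "pierced_lasso" &
    out$loop_size > loop_min & out$loop_size < loop_max
  out$reason <- dplyr::case_when(
    out$keep ~ "retained",
    out$label != "pierced_lasso" ~ paste0("not pierced (", out$label, ")"),
    out$loop_size <= loop_min ~ paste0("loop too small (", out$loop_size, ")"),
    TRUE ~ paste0("loop too large (", out$loop_size, ")")
  )
  dplyr::relocate(out, "structure_id")
}
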