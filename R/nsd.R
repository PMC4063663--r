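#' @title Native-state dynamics (NSD)
#' @description
#' Slow-mode per-residue fluctuation profiles from the folded basin: sample
#' far below the folding temperature, rigid-body align the frames, diagonalize
#' the Calpha displacement covariance, and report the per-residue RMS
#' displacement within the subspace of the first four principal components.
#' Differencing the reduced and oxidized profiles shows whether closing the
#' disulphide changes dynamics only locally around the bridge (an empty
#' loop) or globally (a threaded, pierced-lasso topology).
#' @name nsd
NULL

#' Sample the folded basin below the folding temperature
#'
#' Runs Langevin dynamics at `t_frac * tf`. Retained frames must have
#' Q > `q_min`; discarded frames are counted and more than `max_discard`
#' of them aborts the run (the basin was left too often to call this
#' native-state sampling). A sustained excursion below Q = 0.5 errors
#' immediately with a suggestion to lower `t_frac`.
#'
#' @param topology an `sbm_topology`.
#' @param tf folding temperature of this topology, epsilon.
#' @param t_frac fraction of Tf to sample at (0 < t_frac < 1).
#' @param n_steps,stride,seed run parameters.
#' @param q_min basin membership threshold on Q.
#' @param max_discard maximum tolerated discarded-frame fraction.
#' @param lambda contact tolerance factor for Q.
#' @return a `plasso_traj` restricted to basin frames, with attributes
#'   `retention` and `temperature_frac`.
#' @export
sample_native <- function(topology, tf, t_frac = 0.7, n_steps = 2e5,
                          stride = 50, seed = 1, q_min = 0.85,
                          max_discard = 0.01, lambda = 1.2) {
  if (t_frac <= 0 || t_frac >= 1) stop("t_frac must be in (0, 1)")
  cfg <- run_config(temperature = t_frac * tf, n_steps = n_steps,
                    stride = stride, seed = seed)
  tr <- run_langevin(topology, topology$x_native, cfg)
  q <- tr$Q
  unfold_run <- rle(q < 0.5)
  if (any(unfold_run$values & unfold_run$lengths >= 20)) {
    stop("unfolding detected during native-state sampling (sustained ",
         "Q < 0.5); lower t_frac below ", t_frac)
  }
  keep <- q > q_min
  discard <- 1 - mean(keep)
  if (discard > max_discard) {
    stop("native-state sampling discarded ", round(100 * discard, 1),
         "% of frames (limit ", 100 * max_discard,
         "%); lower t_frac or raise n_steps")
  }
  tr$frames <- tr$frames[keep, , drop = FALSE]
  tr$times <- tr$times[keep]
  tr$e_pot <- tr$e_pot[keep]; tr$e_kin <- tr$e_kin[keep]
  tr$Q <- tr$Q[keep]; tr$Q_smooth <- tr$Q_smooth[keep]
  tr$e_bias <- tr$e_bias[keep]
  attr(tr, "retention") <- 1 - discard
  attr(tr, "temperature_frac") <- t_frac
  tr
}

# Kabsch superposition of each frame onto a reference (3n vectors)
align_frames <- function(frames, n, iters = 2) {
  F <- nrow(frames)
  ref <- matrix(frames[1, ], n, 3, byrow = TRUE)
  ref <- sweep(ref, 2, colMeans(ref))
  for (it in seq_len(iters)) {
    for (f in seq_len(F)) {
      X <- matrix(frames[f, ], n, 3, byrow = TRUE)
      X <- sweep(X, 2, colMeans(X))
      sv <- svd(crossprod(X, ref))
      d <- sign(det(sv$v %*% t(sv$u)))
      R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
      frames[f, ] <- as.numeric(t(X %*% t(R)))
    }
    ref <- matrix(colMeans(frames), n, 3, byrow = TRUE)
  }
  frames
}

#' Per-residue slow-mode fluctuation amplitudes from PCA
#'
#' Frames are rigid-body aligned to their mean, the 3n x 3n covariance of
#' Calpha displacements is diagonalized, and each frame's displacement is
#' projected onto the top `n_components` eigenvectors. The profile is the
#' per-residue RMS of the reconstructed displacement in that subspace,
#' summed over the component subspace and reported in Angstrom.
#'
#' @param traj a `plasso_traj` (e.g. from [sample_native()]).
#' @param n_components number of leading principal components (default 4).
#' @param n_blocks if > 0, additionally compute block-wise amplitude
#'   profiles (contiguous frame blocks, shared eigenvectors) for resampling
#'   tests.
#' @return tibble of class `nsd_profile`: `residue`, `amplitude` (Angstrom);
#'   attributes `eigenvalues`, `blocks` (matrix residue x block or NULL),
#'   `n_frames`.
#' @export
pca_fluctuations <- function(traj, n_components = 4, n_blocks = 0) {
  n <- traj$n
  F <- nrow(traj$frames)
  if (F < 10 * n) {
    stop("need at least 10 frames per residue for a stable covariance (",
         F, " frames, ", n, " residues)")
  }
  aligned <- align_frames(traj$frames, n)
  mu <- colMeans(aligned)
  X <- sweep(aligned, 2, mu)              # F x 3n, displacements
  cv <- crossprod(X) / F
  eg <- eigen(cv, symmetric = TRUE)
  if (sum(eg$values > 1e-12) < n_components) {
    stop("rank-deficient covariance: too few frames for ", n_components,
         " components")
  }
  V <- eg$vectors[, seq_len(n_components), drop = FALSE]

  amp_of <- function(rows) {
    proj <- X[rows, , drop = FALSE] %*% V      # scores
    rec <- proj %*% t(V)                        # back to 3n
    msd <- colMeans(rec^2)                      # per-coordinate
    sqrt(msd[seq(1, 3 * n, 3)] + msd[seq(2, 3 * n, 3)] +
           msd[seq(3, 3 * n, 3)]) * 10         # nm -> Angstrom
  }
  out <- tibble::tibble(residue = seq_len(n), amplitude = amp_of(seq_len(F)))
  blocks <- NULL
  if (n_blocks > 0) {
    cuts <- split(seq_len(F), cut(seq_len(F), n_blocks, labels = FALSE))
    blocks <- vapply(cuts, amp_of, numeric(n))
  }
  attr(out, "eigenvalues") <- eg$values
  attr(out, "blocks") <- blocks
  attr(out, "n_frames") <- F
  class(out) <- c("nsd_profile", class(out))
  out
}

#' Difference of NSD profiles (reduced minus oxidized)
#'
#' @param p_red,p_ox `nsd_profile` objects of equal length.
#' @param bridge internal index pair of the disulphide.
#' @param window half-width (residues) of the local zone around each bridge
#'   cysteine.
#' @return tibble of class `nsd_difference`: `residue`, `amplitude_red`,
#'   `amplitude_ox`, `delta`, `local` (inside the bridge window); attribute
#'   `summary` holds mean |delta| inside/outside.
#' @export
nsd_difference <- function(p_red, p_ox, bridge, window = 10) {
  if (nrow(p_red) != nrow(p_ox)) stop("profile length mismatch")
  ij <- bridge_indices(bridge)
  n <- nrow(p_red)
  local <- rep(FALSE, n)
  for (c0 in ij) {
    local[max(1, c0 - window):min(n, c0 + window)] <- TRUE
  }
  out <- tibble::tibble(
    residue = p_red$residue,
    amplitude_red = p_red$amplitude,
    amplitude_ox = p_ox$amplitude,
    delta = p_red$amplitude - p_ox$amplitude,
    local = local
  )
  attr(out, "summary") <- c(
    mean_abs_delta_local = mean(abs(out$delta[local])),
    mean_abs_delta_distal = mean(abs(out$delta[!local]))
  )
  class(out) <- c("nsd_difference", class(out))
  out
}

#' Permutation test for non-local oxidation effects on NSD
#'
#' Tests whether the reduced/oxidized amplitude difference outside the
#' bridge window exceeds what block-level exchange noise explains. Block
#' profiles (from `pca_fluctuations(..., n_blocks = )`) are pooled and state
#' labels permuted; the statistic is the mean |delta| over distal residues.
#' A large p-value (no signal) is the empty-loop control behaviour: closing
#' an unthreaded loop changes dynamics only near the bridge.
#'
#' @param p_red,p_ox `nsd_profile` objects carrying block matrices.
#' @param bridge internal index pair.
#' @param window local half-width, residues.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list: `p_value`, `observed`, `null` (numeric vector),
#'   `n_blocks`.
#' @export
nsd_permutation_test <- function(p_red, p_ox, bridge, window = 10,
                                 n_perm = 500, seed = 1) {
  br <- attr(p_red, "blocks")
  bo <- attr(p_ox, "blocks")
  if (is.null(br) || is.null(bo)) {
    stop("profiles need block matrices; rerun pca_fluctuations with n_blocks")
  }
  ij <- bridge_indices(bridge)
  n <- nrow(p_red)
  local <- rep(FALSE, n)
  for (c0 in ij) local[max(1, c0 - window):min(n, c0 + window)] <- TRUE
  distal <- !local

  all_blocks <- cbind(br, bo)
  lab <- c(rep(1L, ncol(br)), rep(2L, ncol(bo)))
  stat <- function(labels) {
    m1 <- rowMeans(all_blocks[, labels == 1L, drop = FALSE])
    m2 <- rowMeans(all_blocks[, labels == 2L, drop = FALSE])
    mean(abs(m1 - m2)[distal])
  }
  observed <- stat(lab)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(k) stat(sample(lab)), numeric(1))
  list(p_value = (1 + sum(null >= observed)) / (1 + n_perm),
       observed = observed, null = null,
       n_blocks = ncol(all_blocks))
}

#' Write an NSD comparison to TSV
#'
#' @param d an `nsd_difference` tibble.
#' @param path output file.
#' @export
write_nsd <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
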