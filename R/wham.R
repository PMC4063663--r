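#' @title Weighted Histogram Analysis Method
#' @description
#' Multi-histogram reweighting (Ferrenberg-Swendsen self-consistent
#' iteration) in two flavours: temperature WHAM on potential-energy samples,
#' yielding a relative density of states, the specific-heat curve Cv(T) and
#' the folding temperature Tf at its maximum; and umbrella WHAM on biased Q
#' histograms, yielding the unbiased free-energy profile F(Q). Reduced
#' units: k_B = 1, temperatures and energies in epsilon, so the
#' configurational specific heat of a 1-D harmonic oscillator is exactly
#' 1/2.
#' @name wham
NULL

#' Temperature WHAM: density of states and Cv(T)
#'
#' @param energies list of numeric vectors, potential-energy samples per run.
#' @param temperatures one temperature (epsilon) per run.
#' @param n_bins number of energy bins on the pooled range.
#' @param t_grid temperatures at which to evaluate Cv; defaults to a fine
#'   grid spanning the sampled range.
#' @param tol relative convergence tolerance on the free energies.
#' @param max_iter iteration cap.
#' @return object of class `thermo_result`: a list with the energy grid and
#'   relative log density of states, the `cv` tibble (`T`, `E_mean`, `Cv`)
#'   and `Tf` (grid argmax of Cv).
#' @export
wham_cv <- function(energies, temperatures, n_bins = 120, t_grid = NULL,
                    tol = 1e-8, max_iter = 10000) {
  stopifnot(length(energies) == length(temperatures), length(energies) >= 1)
  check_histogram_overlap(energies)
  pooled <- unlist(energies)
  rng <- range(pooled)
  breaks <- seq(rng[1], rng[2] + 1e-9 * max(1, abs(rng[2])),
                length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- vapply(energies, function(e) {
    tabulate(pmin(pmax(findInterval(e, breaks, rightmost.closed = TRUE), 1),
                  n_bins), n_bins)
  }, numeric(n_bins))          # n_bins x n_runs
  n_samp <- vapply(energies, length, numeric(1))
  betas <- 1 / temperatures
  n_tot <- rowSums(counts)

  # self-consistent iteration in log space
  lf <- rep(0, length(energies))     # log e^{f_i} (dimensionless free energies)
  for (it in seq_len(max_iter)) {
    # log denominator per bin: log sum_i n_i exp(lf_i - beta_i E_k)
    lden <- vapply(seq_len(n_bins), function(k) {
      logsumexp(log(n_samp) + lf - betas * mids[k])
    }, numeric(1))
    lg <- ifelse(n_tot > 0, log(n_tot) - lden, -Inf)
    lf_new <- -vapply(seq_along(betas), function(i) {
      logsumexp(lg[is.finite(lg)] - betas[i] * mids[is.finite(lg)])
    }, numeric(1))
    lf_new <- lf_new - lf_new[1]
    if (max(abs(lf_new - lf)) < tol * max(1, max(abs(lf_new)))) {
      lf <- lf_new
      break
    }
    lf <- lf_new
  }
  lden <- vapply(seq_len(n_bins), function(k) {
    logsumexp(log(n_samp) + lf - betas * mids[k])
  }, numeric(1))
  lg <- ifelse(n_tot > 0, log(n_tot) - lden, -Inf)

  if (is.null(t_grid)) {
    t_grid <- seq(min(temperatures) * 0.8, max(temperatures) * 1.2,
                  length.out = 400)
  }
  keep <- is.finite(lg)
  cv <- purrr::map_dfr(t_grid, function(Tt) {
    lw <- lg[keep] - mids[keep] / Tt
    lz <- logsumexp(lw)
    w <- exp(lw - lz)
    e1 <- sum(w * mids[keep])
    e2 <- sum(w * mids[keep]^2)
    tibble::tibble(T = Tt, E_mean = e1, Cv = max(0, (e2 - e1^2) / Tt^2))
  })
  out <- list(E = mids, log_dos = lg, cv = cv,
              Tf = cv$T[which.max(cv$Cv)],
              temperatures = temperatures)
  class(out) <- "thermo_result"
  out
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("# WHAM thermodynamics from", length(x$temperatures), "runs; Tf =",
      signif(x$Tf, 4), "eps (Cv peak)\n")
  invisible(x)
}

#' Umbrella WHAM: unbiased free-energy profile F(Q)
#'
#' Unbiases harmonic umbrella windows sampled at one temperature. The
#' histogrammed coordinate is the same smooth Q the bias acted on.
#'
#' @param q_samples list of numeric vectors (per-window smooth-Q samples).
#' @param q_centers,k_umbs per-window bias parameters.
#' @param temperature run temperature, epsilon.
#' @param n_bins Q bins on [0, 1].
#' @param tol,max_iter iteration control.
#' @return tibble with `Q`, `F` (epsilon; minimum shifted to 0) and `count`;
#'   attribute `log_f` holds the window free energies.
#' @export
wham_fq <- function(q_samples, q_centers, k_umbs, temperature = 1.0,
                    n_bins = 50, tol = 1e-8, max_iter = 10000) {
  stopifnot(length(q_samples) == length(q_centers),
            length(q_samples) == length(k_umbs))
  check_histogram_overlap(q_samples)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- vapply(q_samples, function(qv) {
    tabulate(pmin(pmax(findInterval(qv, breaks, rightmost.closed = TRUE), 1),
                  n_bins), n_bins)
  }, numeric(n_bins))
  n_samp <- vapply(q_samples, length, numeric(1))
  n_tot <- rowSums(as.matrix(counts))
  # bias energy of window i at bin k, over T
  cmat <- outer(mids, seq_along(q_centers),
                function(q, i) 0.5 * k_umbs[i] * (q - q_centers[i])^2) /
    temperature

  lf <- rep(0, length(q_samples))
  for (it in seq_len(max_iter)) {
    lden <- vapply(seq_len(n_bins), function(k) {
      logsumexp(log(n_samp) + lf - cmat[k, ])
    }, numeric(1))
    lp <- ifelse(n_tot > 0, log(n_tot) - lden, -Inf)
    lf_new <- -vapply(seq_along(q_samples), function(i) {
      sel <- is.finite(lp)
      logsumexp(lp[sel] - cmat[sel, i])
    }, numeric(1))
    lf_new <- lf_new - lf_new[1]
    if (max(abs(lf_new - lf)) < tol * max(1, max(abs(lf_new)))) {
      lf <- lf_new
      break
    }
    lf <- lf_new
  }
  lden <- vapply(seq_len(n_bins), function(k) {
    logsumexp(log(n_samp) + lf - cmat[k, ])
  }, numeric(1))
  lp <- ifelse(n_tot > 0, log(n_tot) - lden, -Inf)
  Fq <- -temperature * lp
  Fq <- Fq - min(Fq[is.finite(Fq)])
  out <- tibble::tibble(Q = mids, F = Fq, count = n_tot)
  attr(out, "log_f") <- lf
  out
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# WHAM needs every run's histogram to overlap some other run's; otherwise
# the relative free energies are undetermined. Report the overlap matrix.
check_histogram_overlap <- function(samples) {
  k <- length(samples)
  if (k == 1) return(invisible(TRUE))
  rngs <- lapply(samples, range)
  ov <- matrix(FALSE, k, k)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      ov[a, b] <- ov[b, a] <-
        rngs[[a]][1] <= rngs[[b]][2] && rngs[[b]][1] <= rngs[[a]][2]
    }
  }
  # connectivity by BFS
  seen <- logical(k)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[1]
    queue <- queue[-1]
    nb <- which(ov[cur, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen)) {
    stop("histograms do not overlap into a connected set; overlap matrix:\n",
         paste(utils::capture.output(print(ov * 1)), collapse = "\n"))
  }
  invisible(TRUE)
}
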