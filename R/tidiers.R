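#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.thermo_result <- function(x, ...) {
  x$cv
}

#' @exportS3Method generics::glance
glance.thermo_result <- function(x, ...) {
  tibble::tibble(
    Tf = x$Tf,
    Cv_max = max(x$cv$Cv),
    n_runs = length(x$temperatures),
    T_min = min(x$temperatures),
    T_max = max(x$temperatures)
  )
}

#' @exportS3Method generics::tidy
tidy.mechanism_curves <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::tidy
tidy.nsd_profile <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.nsd_profile <- function(x, ...) {
  ev <- attr(x, "eigenvalues")
  tibble::tibble(
    n_residues = nrow(x),
    n_frames = attr(x, "n_frames"),
    var_top4 = sum(ev[1:4]) / sum(ev)
  )
}

#' @exportS3Method generics::tidy
tidy.nsd_difference <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @exportS3Method generics::glance
glance.nsd_difference <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(
    mean_abs_delta_local = s[["mean_abs_delta_local"]],
    mean_abs_delta_distal = s[["mean_abs_delta_distal"]]
  )
}
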