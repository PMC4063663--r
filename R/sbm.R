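#' @title Calpha structure-based (Go-type) model
#' @description
#' Builds the coarse-grained native-centric Hamiltonian: harmonic bonds
#' (k_b = 2e4 epsilon/nm^2) between consecutive residues, harmonic angles
#' (k_a = 40 epsilon/rad^2), cosine dihedrals (k_d1 = epsilon,
#' k_d2 = 0.5 epsilon with the 3-fold term), Gaussian-well native contacts
#' anchored at -epsilon at the native separation, and a generic
#' (sigma/r)^12 excluded volume with sigma = 4 A. Internal units are nm for
#' lengths, epsilon for energies, k_B = 1, masses 1.
#' @name sbm
NULL

#' Build a native contact map
#'
#' `ca_cutoff`: residue pairs with native Calpha separation below `cutoff`
#' (default 8 A) and sequence separation at least `min_seq_sep` (default 4).
#' `shadow_approx` additionally removes pairs whose connecting segment passes
#' within `screen_radius` (default 1 A) of a third residue's Calpha - a
#' Calpha-level approximation of shadow-map screening.
#'
#' @param s a `plasso_structure`.
#' @param method `"ca_cutoff"` or `"shadow_approx"`.
#' @param cutoff contact distance cutoff, Angstrom.
#' @param min_seq_sep minimum |i - j|.
#' @param screen_radius shadow screening radius, Angstrom.
#' @return tibble with columns `i`, `j` (internal indices, i < j) and
#'   `r0` (native separation, nm).
#' @export
build_contact_map <- function(s, method = c("ca_cutoff", "shadow_approx"),
                              cutoff = 8.0, min_seq_sep = 4,
                              screen_radius = 1.0) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("cutoff must be positive")
  br <- chain_breaks(s)
  if (nrow(br) > 0) {
    stop("structure has chain break(s) (first after residue ",
         br$resid_before[1], "); model the gap-free range")
  }
  ca <- ca_coords(s)
  n <- nrow(ca)
  dd <- as.matrix(stats::dist(ca))
  sel <- which(upper.tri(dd) & dd < cutoff &
                 abs(row(dd) - col(dd)) >= min_seq_sep, arr.ind = TRUE)
  if (nrow(sel) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), r0 = numeric()))
  }
  cm <- tibble::tibble(i = pmin(sel[, 1], sel[, 2]),
                       j = pmax(sel[, 1], sel[, 2]))
  cm$r0 <- dd[cbind(cm$i, cm$j)] / 10   # Angstrom -> nm
  cm <- dplyr::arrange(cm, .data$i, .data$j)

  if (method == "shadow_approx") {
    keep <- vapply(seq_len(nrow(cm)), function(k) {
      a <- ca[cm$i[k], ]; b <- ca[cm$j[k], ]
      ab <- b - a
      len2 <- sum(ab^2)
      others <- setdiff(seq_len(n), c(cm$i[k], cm$j[k]))
      for (m in others) {
        t0 <- sum((ca[m, ] - a) * ab) / len2
        if (t0 <= 0 || t0 >= 1) next
        d <- sqrt(sum((a + t0 * ab - ca[m, ])^2))
        if (d < screen_radius) return(FALSE)
      }
      TRUE
    }, logical(1))
    cm <- cm[keep, , drop = FALSE]
  }
  cm
}

#' Build the structure-based topology under a disulphide oxidation state
#'
#' The bridge enters the model according to `state`:
#' * `oxidized`: an unbreakable harmonic bond at the native separation;
#' * `dynamic`: a breakable Gaussian contact of depth `eps_ss` (a
#'   native-like interaction that can form and break during folding);
#' * `reduced`: excluded volume only - the pair is removed from the contact
#'   map and the loop has no covalent closure.
#'
#' @param s a `plasso_structure` (gap-free over the modeled range).
#' @param contacts contact map from [build_contact_map()]; built with
#'   defaults when `NULL`.
#' @param bridge disulphide pair (row from [detect_disulphides()] or internal
#'   index pair); `NULL` for a bridge-free model.
#' @param state `"oxidized"`, `"reduced"` or `"dynamic"`.
#' @param eps_ss depth of the dynamic disulphide contact, epsilon.
#' @param width Gaussian contact well width, nm (0.05 nm = 0.5 A).
#' @param k_bond,k_angle,k_dih1,k_dih3 force constants (reduced units).
#' @param k_ss stiffness of the oxidized disulphide bond, epsilon/nm^2.
#'   The covalent link runs through four side-chain bonds, so its
#'   effective Calpha-Calpha stiffness is far below the backbone virtual
#'   bond; 500 keeps the closure tight (thermal extension ~0.05 nm at
#'   folding temperatures) and unbreakable.
#' @param sigma excluded-volume diameter, nm (0.4 nm = 4 A).
#' @return an object of class `sbm_topology`.
#' @export
build_topology <- function(s, contacts = NULL, bridge = NULL,
                           state = c("oxidized", "reduced", "dynamic"),
                           eps_ss = 1.0, width = 0.05,
                           k_bond = 2e4, k_angle = 40, k_dih1 = 1,
                           k_dih3 = 0.5, k_ss = 500, sigma = 0.4) {
  state <- match.arg(state)
  if (is.null(contacts)) contacts <- build_contact_map(s)
  ca <- ca_coords(s) / 10   # nm
  n <- nrow(ca)
  if (n < 4) stop("need at least 4 residues")

  ij <- if (is.null(bridge)) NULL else bridge_indices(bridge)
  if (!is.null(ij) && diff(ij) < 2) stop("disulphide pair inside bonded neighbors")

  bonds <- cbind(1:(n - 1), 2:n,
                 sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2)),
                 k_bond)
  angles <- t(vapply(1:(n - 2), function(i) {
    c(i, i + 1, i + 2, vec_angle(ca[i, ] - ca[i + 1, ], ca[i + 2, ] - ca[i + 1, ]),
      k_angle)
  }, numeric(5)))
  dihedrals <- t(vapply(1:(n - 3), function(i) {
    c(i, i + 1, i + 2, i + 3,
      vec_dihedral(ca[i, ], ca[i + 1, ], ca[i + 2, ], ca[i + 3, ]),
      k_dih1, k_dih3)
  }, numeric(7)))

  cm <- contacts
  ss_contact <- NULL
  ss_bond <- NULL
  if (!is.null(ij)) {
    d_ss <- sqrt(sum((ca[ij[1], ] - ca[ij[2], ])^2))
    in_map <- which(cm$i == ij[1] & cm$j == ij[2])
    if (state == "oxidized") {
      if (length(in_map) > 0) cm <- cm[-in_map, , drop = FALSE]
      ss_bond <- c(ij[1], ij[2], d_ss, k_ss)
    } else if (state == "dynamic") {
      if (length(in_map) > 0) cm <- cm[-in_map, , drop = FALSE]
      ss_contact <- c(ij[1], ij[2], d_ss, eps_ss, width)
    } else {
      if (length(in_map) > 0) cm <- cm[-in_map, , drop = FALSE]
    }
  }

  cmat <- if (nrow(cm) > 0) {
    cbind(cm$i, cm$j, cm$r0, 1.0, width)
  } else {
    matrix(numeric(0), 0, 5)
  }
  if (!is.null(ss_contact)) cmat <- rbind(cmat, ss_contact)
  bmat <- bonds
  if (!is.null(ss_bond)) bmat <- rbind(bmat, ss_bond)

  # pairs excluded from generic repulsion: native contacts carry their own
  # core; an oxidized/dynamic SS pair is governed by its bond/contact; a
  # reduced SS pair keeps plain repulsion (no special treatment)
  excl <- cmat[, 1:2, drop = FALSE]
  if (!is.null(ss_bond)) excl <- rbind(excl, ss_bond[1:2])
  storage.mode(excl) <- "integer"

  topo <- list(
    n = n,
    bonds = bmat,
    angles = angles,
    dihedrals = dihedrals,
    contacts = cmat,
    rep_excl = excl,
    sigma = sigma,
    eps_rep = 1.0,
    rcut = 1.2,
    min_rep_sep = 3L,
    state = state,
    bridge = ij,
    eps_ss = eps_ss,
    width = width,
    x_native = ca,
    contact_map = cm
  )
  class(topo) <- "sbm_topology"
  topo
}

vec_angle <- function(u, v) {
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

vec_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- crossprod3(b1, b2); n2 <- crossprod3(b2, b3)
  m1 <- crossprod3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

#' @export
print.sbm_topology <- function(x, ...) {
  cat("# sbm topology: ", x$n, " residues, ", nrow(x$bonds), " bonds, ",
      nrow(x$contacts), " contacts, state ", x$state,
      if (!is.null(x$bridge)) paste0(", SS ", x$bridge[1], "-", x$bridge[2]),
      "\n", sep = "")
  cat("# sigma ", x$sigma, " nm, contact width ", x$width, " nm\n", sep = "")
  invisible(x)
}

#' Potential energy with per-term breakdown
#'
#' At the native coordinates the bond, angle and dihedral terms vanish and
#' the contact term equals -epsilon times the number of contacts (each
#' Gaussian well is anchored at exactly -epsilon at its native separation).
#'
#' @param topology an `sbm_topology`.
#' @param coords n x 3 coordinates, nm.
#' @return tibble with one row: `total`, `bond`, `angle`, `dihedral`,
#'   `contact`, `repulsive` (all epsilon).
#' @export
sbm_energy <- function(topology, coords) {
  e <- cpp_sbm_energy(unclass(topology), coords)
  tibble::as_tibble(e[c("total", "bond", "angle", "dihedral", "contact",
                        "repulsive")])
}

#' Analytic forces, -grad E
#'
#' @param topology an `sbm_topology`.
#' @param coords n x 3 coordinates, nm.
#' @return n x 3 matrix of forces, epsilon/nm.
#' @export
sbm_forces <- function(topology, coords) {
  cpp_sbm_forces(unclass(topology), coords)
}

#' Serialize a topology to a sectioned TSV text file
#'
#' Sections (`[bonds]`, `[angles]`, `[dihedrals]`, `[contacts]`) with
#' tab-separated numeric columns; header lines carry the model constants so
#' a run is reproducible from the file alone.
#'
#' @param topology an `sbm_topology`.
#' @param path output file.
#' @export
write_topology <- function(topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# sbm topology  n=", topology$n, " state=", topology$state),
    paste0("# sigma_nm=", topology$sigma, " width_nm=", topology$width,
           " eps_ss=", topology$eps_ss),
    if (!is.null(topology$bridge)) {
      paste0("# ss_pair=", topology$bridge[1], ",", topology$bridge[2])
    }
  ), con)
  dump_sec <- function(name, m, cols) {
    writeLines(paste0("[", name, "]"), con)
    writeLines(paste(cols, collapse = "\t"), con)
    if (nrow(m) > 0) {
      utils::write.table(m, con, sep = "\t", row.names = FALSE,
                         col.names = FALSE)
    }
  }
  dump_sec("bonds", topology$bonds, c("i", "j", "r0_nm", "k"))
  dump_sec("angles", topology$angles, c("i", "j", "k", "theta0_rad", "ka"))
  dump_sec("dihedrals", topology$dihedrals,
           c("i", "j", "k", "l", "phi0_rad", "k1", "k3"))
  dump_sec("contacts", topology$contacts, c("i", "j", "r0_nm", "eps", "w_nm"))
  invisible(path)
}
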