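#' Protein structures as residue-level tibbles
#'
#' A `plasso_structure` is a tibble with one row per resolved residue and
#' columns `resid` (author numbering), `aa` (one-letter code), `x`, `y`, `z`
#' (Calpha coordinates, Angstrom), `sgx`, `sgy`, `sgz` (cysteine SG
#' coordinates, `NA` elsewhere) and `chain`. Internal indexing is the row
#' number (1-based, contiguous over resolved residues); author numbering is
#' kept as metadata so bridges can be quoted the way crystallographers do
#' (e.g. C96-C146).
#'
#' @param resid integer vector of author residue numbers, strictly increasing.
#' @param aa character vector of one-letter amino-acid codes.
#' @param ca numeric matrix (n x 3) of Calpha coordinates in Angstrom.
#' @param sg optional numeric matrix (n x 3) of SG coordinates (`NA` rows for
#'   non-cysteines).
#' @param chain chain identifier.
#' @return A `plasso_structure` tibble.
#' @export
new_structure <- function(resid, aa, ca, sg = NULL, chain = "A") {
  n <- length(resid)
  stopifnot(length(aa) == n, nrow(ca) == n)
  if (n > 0 && any(diff(resid) <= 0)) {
    stop("residue numbering must be strictly increasing")
  }
  if (is.null(sg)) sg <- matrix(NA_real_, n, 3)
  tibble::new_tibble(
    tibble::tibble(
      resid = as.integer(resid), aa = as.character(aa),
      x = ca[, 1], y = ca[, 2], z = ca[, 3],
      sgx = sg[, 1], sgy = sg[, 2], sgz = sg[, 3],
      chain = chain
    ),
    class = "plasso_structure"
  )
}

#' @export
ca_coords <- function(s) {
  as.matrix(s[, c("x", "y", "z")])
}

#' Read a Calpha trace (plus cysteine sulfurs) from a PDB file
#'
#' Parses the file with [bio3d::read.pdb()], keeps the requested chain and
#' model, and returns the Calpha trace in file order. Residues without a
#' Calpha atom are dropped with a warning; SG coordinates are retained for
#' cysteines when present.
#'
#' @param path PDB file.
#' @param chain chain identifier; defaults to the first chain in the file.
#' @param model model index for multi-model (NMR) files; default 1.
#' @return A [new_structure()] tibble.
#' @export
read_structure <- function(path, chain = NULL, model = 1) {
  pdb <- bio3d::read.pdb(path, multi = model > 1, verbose = FALSE)
  at <- pdb$atom
  if (model > 1) {
    nmod <- nrow(pdb$xyz)
    if (model > nmod) stop("model ", model, " requested but file has ", nmod)
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains) {
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "))
  }
  at <- at[at$chain == chain & at$type %in% c("ATOM", "HETATM"), , drop = FALSE]

  res_all <- unique(at$resno[at$elety %in% c("CA", "SG")])
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]  # first altloc wins
  missing_ca <- setdiff(unique(at$resno), ca$resno)
  if (length(missing_ca) > 0) {
    warning(length(missing_ca), " residue(s) without a Calpha dropped: ",
            paste(utils::head(missing_ca, 5), collapse = ", "),
            if (length(missing_ca) > 5) ", ..." else "")
  }
  if (nrow(ca) == 0) stop("no Calpha atoms in chain '", chain, "'")
  ord <- order(ca$resno)
  ca <- ca[ord, , drop = FALSE]

  sg <- at[at$elety == "SG", , drop = FALSE]
  sgm <- matrix(NA_real_, nrow(ca), 3)
  if (nrow(sg) > 0) {
    m <- match(ca$resno, sg$resno)
    ok <- !is.na(m)
    sgm[ok, ] <- cbind(sg$x[m[ok]], sg$y[m[ok]], sg$z[m[ok]])
  }
  aa1 <- bio3d::aa321(ca$resid)
  aa1[is.na(aa1)] <- "X"
  new_structure(ca$resno, aa1, cbind(ca$x, ca$y, ca$z), sgm, chain = chain)
}

#' Write a structure back to PDB
#'
#' Emits standard ATOM records (Calpha per residue, SG for cysteines with
#' sulfur coordinates), preserving author numbering.
#'
#' @param s a `plasso_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  if (nrow(s) == 0) stop("refusing to write an empty structure")
  has_sg <- !is.na(s$sgx)
  rec <- function(i, elety) {
    if (elety == "CA") c(s$x[i], s$y[i], s$z[i]) else c(s$sgx[i], s$sgy[i], s$sgz[i])
  }
  rows <- list()
  for (i in seq_len(nrow(s))) {
    rows[[length(rows) + 1]] <- list(i = i, elety = "CA", xyz = rec(i, "CA"))
    if (has_sg[i]) {
      rows[[length(rows) + 1]] <- list(i = i, elety = "SG", xyz = rec(i, "SG"))
    }
  }
  xyz <- as.numeric(vapply(rows, function(r) r$xyz, numeric(3)))
  idx <- vapply(rows, function(r) r$i, integer(1))
  elety <- vapply(rows, function(r) r$elety, character(1))
  aa3 <- bio3d::aa123(s$aa[idx])
  aa3[is.na(aa3) | aa3 == "X"] <- "ALA"
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = s$resid[idx], resid = aa3, eleno = seq_along(idx),
    elety = elety, chain = s$chain[idx]
  )
  invisible(path)
}

#' Detect disulphide bridges
#'
#' Pairs cysteines whose SG-SG distance is below `sg_cutoff` (default 2.5 A)
#' when sulfur coordinates exist; cysteines without sulfurs fall back to a
#' Calpha-Calpha criterion (`ca_cutoff`, default 7 A, chosen because bonded
#' cystines sit at Calpha separations of about 4.5-6.5 A). Each cysteine joins
#' at most one bridge; pairing is greedy nearest-first.
#'
#' @param s a `plasso_structure`.
#' @param sg_cutoff SG-SG distance cutoff, Angstrom.
#' @param ca_cutoff Calpha-Calpha fallback cutoff, Angstrom.
#' @return tibble with one row per bridge: internal indices `i` < `j`, author
#'   numbers `resid_i`, `resid_j`, the measured `distance` and the `method`
#'   used (`"sg"` or `"ca"`). Zero rows when no bridge is found.
#' @export
detect_disulphides <- function(s, sg_cutoff = 2.5, ca_cutoff = 7.0) {
  empty <- tibble::tibble(
    i = integer(), j = integer(), resid_i = integer(), resid_j = integer(),
    distance = numeric(), method = character()
  )
  cys <- which(s$aa == "C")
  if (length(cys) < 2) return(empty)

  pairs <- utils::combn(cys, 2)
  cand <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (j - i < 2) return(NULL)
    if (!is.na(s$sgx[i]) && !is.na(s$sgx[j])) {
      d <- sqrt(sum((c(s$sgx[i], s$sgy[i], s$sgz[i]) -
                       c(s$sgx[j], s$sgy[j], s$sgz[j]))^2))
      if (d < sg_cutoff) {
        return(tibble::tibble(i = i, j = j, distance = d, method = "sg"))
      }
    } else {
      d <- sqrt(sum((ca_coords(s)[i, ] - ca_coords(s)[j, ])^2))
      if (d < ca_cutoff) {
        return(tibble::tibble(i = i, j = j, distance = d, method = "ca"))
      }
    }
    NULL
  })
  if (nrow(cand) == 0) return(empty)

  cand <- dplyr::arrange(cand, .data$distance)
  used <- integer()
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!(cand$i[k] %in% used) && !(cand$j[k] %in% used)) {
      keep[k] <- TRUE
      used <- c(used, cand$i[k], cand$j[k])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out$resid_i <- s$resid[out$i]
  out$resid_j <- s$resid[out$j]
  dplyr::arrange(out[, c("i", "j", "resid_i", "resid_j", "distance", "method")],
                 .data$i)
}

#' Locate chain breaks
#'
#' A break is a gap in author numbering or a consecutive Calpha-Calpha
#' distance outside the virtual-bond range. Topology analysis refuses to span
#' a break inside a covalent loop.
#'
#' @param s a `plasso_structure`.
#' @param max_dist maximum consecutive Calpha-Calpha distance, Angstrom.
#' @return tibble with columns `after` (internal index before the break),
#'   `resid_before`, `resid_after`, `reason`.
#' @export
chain_breaks <- function(s, max_dist = 4.5) {
  n <- nrow(s)
  if (n < 2) {
    return(tibble::tibble(after = integer(), resid_before = integer(),
                          resid_after = integer(), reason = character()))
  }
  ca <- ca_coords(s)
  d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  gap <- diff(s$resid) != 1L
  far <- d > max_dist
  idx <- which(gap | far)
  tibble::tibble(
    after = idx,
    resid_before = s$resid[idx],
    resid_after = s$resid[idx + 1],
    reason = ifelse(gap[idx] & far[idx], "numbering+distance",
                    ifelse(gap[idx], "numbering", "distance"))
  )
}

#' Validate structure invariants
#'
#' Checks strictly increasing numbering and, over gap-free segments, that the
#' consecutive Calpha-Calpha virtual bonds stay within 2.8-4.5 Angstrom.
#'
#' @param s a `plasso_structure`.
#' @param min_dist,max_dist virtual-bond range, Angstrom.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_structure <- function(s, min_dist = 2.8, max_dist = 4.5) {
  if (any(diff(s$resid) <= 0)) stop("residue numbering not strictly increasing")
  n <- nrow(s)
  if (n < 2) return(invisible(TRUE))
  ca <- ca_coords(s)
  d <- sqrt(rowSums((ca[-1, , drop = FALSE] - ca[-n, , drop = FALSE])^2))
  contiguous <- diff(s$resid) == 1L
  bad <- which(contiguous & (d < min_dist | d > max_dist))
  if (length(bad) > 0) {
    stop("virtual bond out of [", min_dist, ", ", max_dist, "] A after residue ",
         s$resid[bad[1]], " (", round(d[bad[1]], 2), " A)")
  }
  invisible(TRUE)
}

#' @export
print.plasso_structure <- function(x, ...) {
  cat("# plasso structure: ", nrow(x), " residues, chain ",
      unique(x$chain)[1], ", ", sum(x$aa == "C"), " cysteine(s)\n", sep = "")
  NextMethod()
}
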