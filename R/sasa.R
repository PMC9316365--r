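# van der Waals radii (Angstrom) for the elements seen in protein heavy
# atoms; unlisted elements fall back to carbon
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85)

# theoretical maximum accessible surface areas per residue type
# (Tien et al. style Gly-X-Gly maxima, Angstrom^2); non-standard residues
# fall back to the glycine value
.max_sasa <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

# deterministic unit sphere point set (Fibonacci / golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Shrake-Rupley rolling-probe SASA per heavy atom
atom_sasa <- function(coords, radii, probe = 1.4, n_points = 92) {
  n <- nrow(coords)
  pts <- sphere_points(n_points)
  rs <- radii + probe
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    ci <- coords[i, ]
    d2 <- (coords[, 1] - ci[1])^2 + (coords[, 2] - ci[2])^2 +
      (coords[, 3] - ci[3])^2
    nb <- which(d2 > 0 & d2 < (rs[i] + rs)^2)
    test <- sweep(pts * rs[i], 2, ci, "+")
    if (length(nb) > 0) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (test[, 1] - coords[j, 1])^2 + (test[, 2] - coords[j, 2])^2 +
          (test[, 3] - coords[j, 3])^2
        free <- free & dj2 > rs[j]^2
        if (!any(free)) break
      }
      frac <- sum(free) / n_points
    } else {
      frac <- 1
    }
    sasa[i] <- 4 * pi * rs[i]^2 * frac
  }
  sasa
}

#' Solvent accessibility and surface-residue count for a chain
#'
#' Computes per-residue solvent-accessible surface area with a rolling
#' probe (Shrake-Rupley point sampling, probe radius 1.4 A, heavy atoms
#' only), converts it to relative accessibility against per-residue-type
#' theoretical maxima, and flags residues at or above the exposure
#' threshold as surface residues. The count of surface residues is the R
#' that drives the dynamic classification cutoff.
#'
#' @param structure atom tibble (see [read_structure()]).
#' @param chain chain to evaluate.
#' @param threshold relative-accessibility threshold in (0, 1); default
#'   0.05, i.e. 5% of the residue-type maximum.
#' @param probe probe radius in Angstrom.
#' @param n_points sphere sample points per atom; more points, finer SASA.
#' @param context `"chain"` (default) computes exposure of the isolated
#'   chain; `"complex"` leaves all chains in place so partner chains bury
#'   surface.
#' @return tibble with `chain`, `resno`, `icode`, `resid`, `sasa`,
#'   `rel_acc` (clipped to \[0, 1\]), `surface` (logical); attributes
#'   `"R"` (surface-residue count) and `"threshold"`.
#' @export
surface_residues <- function(structure, chain, threshold = 0.05,
                             probe = 1.4, n_points = 92,
                             context = c("chain", "complex")) {
  context <- match.arg(context)
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be strictly between 0 and 1")
  }
  atoms <- structure |> filter(.data$element != "H")
  if (context == "chain") atoms <- atoms |> filter(.data$chain == !!chain)
  if (nrow(atoms |> filter(.data$chain == !!chain)) == 0) {
    abort(sprintf("chain '%s' has no heavy atoms", chain))
  }
  radii <- unname(.vdw_radii[atoms$element])
  radii[is.na(radii)] <- .vdw_radii[["C"]]
  sasa <- atom_sasa(as.matrix(atoms[, c("x", "y", "z")]), radii,
                    probe = probe, n_points = n_points)

  out <- atoms |>
    mutate(.sasa = sasa) |>
    filter(.data$chain == !!chain) |>
    group_by(.data$chain, .data$resno, .data$icode, .data$resid) |>
    summarise(sasa = sum(.data$.sasa), .groups = "drop") |>
    mutate(
      max_sasa = unname(.max_sasa[.data$resid]),
      max_sasa = ifelse(is.na(.data$max_sasa), .max_sasa[["GLY"]],
                        .data$max_sasa),
      rel_acc = pmin(1, .data$sasa / .data$max_sasa),
      surface = .data$rel_acc >= threshold
    ) |>
    select(-"max_sasa")
  # restore file order (grouping sorts)
  ord <- chain_residues(structure, chain) |>
    mutate(.ord = dplyr::row_number())
  out <- out |>
    left_join(ord, by = c("chain", "resno", "icode", "resid")) |>
    arrange(.data$.ord) |>
    select(-".ord")
  attr(out, "R") <- sum(out$surface)
  attr(out, "threshold") <- threshold
  out
}

#' Surface-residue count R
#'
#' @param surface tibble from [surface_residues()].
#' @return integer count of surface-exposed residues.
#' @export
surface_count <- function(surface) {
  as.integer(sum(surface$surface))
}
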