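#' Read a protein structure into an atom tibble
#'
#' Parses PDB-format coordinates (via [bio3d::read.pdb()]) into the flat
#' atom table used throughout the package: one row per atom with chain,
#' residue number, insertion code, residue name, atom name, element and
#' Cartesian coordinates in Angstrom. Alternate locations are resolved to
#' the highest-occupancy conformer; HETATM records and waters are dropped
#' unless requested.
#'
#' @param pdb path to a PDB file, or a character scalar/vector holding
#'   PDB-format text directly.
#' @param include_hetatm keep non-water HETATM records? Default `FALSE`.
#' @return a tibble with columns `chain`, `resno`, `icode`, `resid`,
#'   `elety` (atom name), `element`, `x`, `y`, `z`, `occ`. Per-chain
#'   residue order follows the file.
#' @export
read_structure <- function(pdb, include_hetatm = FALSE) {
  lines <- if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    readLines(pdb, warn = FALSE)
  } else {
    unlist(strsplit(pdb, "\n", fixed = TRUE))
  }
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) abort("no ATOM records found in PDB input")
  # validate coordinate fields up front so errors carry the line number
  for (i in which(is_atom)) {
    coords <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords)))) {
      abort(sprintf("malformed coordinate field at line %d: %s",
                    i, trimws(lines[i])))
    }
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb_obj <- suppressWarnings(bio3d::read.pdb(tmp, verbose = FALSE,
                                              rm.alt = FALSE))
  at <- pdb_obj$atom

  keep <- at$type == "ATOM"
  if (include_hetatm) {
    keep <- keep | (at$type == "HETATM" & !at$resid %in% c("HOH", "WAT", "DOD"))
  }
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) abort("structure contains no usable atoms")

  element <- at$elesy
  bad <- is.na(element) | element == ""
  if (any(bad)) element[bad] <- infer_element(at$elety[bad])

  out <- tibble(
    chain = at$chain,
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert) | at$insert == " ", "", at$insert),
    resid = at$resid,
    elety = at$elety,
    element = toupper(element),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt) | at$alt == " ", "", at$alt)
  )
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    abort("non-finite coordinates after parsing")
  }

  # altloc resolution: keep the highest-occupancy conformer per atom slot,
  # ties broken by altloc letter order
  out <- out |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$chain, .data$resno, .data$icode, .data$elety) |>
    arrange(dplyr::desc(.data$occ), .data$alt, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$.row) |>
    select(-".row", -"alt")
  out
}

# element from the atom-name column when the element field is absent
# (common in generated/toy PDB files)
infer_element <- function(elety) {
  e <- sub("^[0-9']+", "", trimws(elety))
  ifelse(grepl("^H", e), "H", substr(e, 1, 1))
}

#' Serialize an atom tibble to PDB-format text
#'
#' Writes minimal ATOM records (occupancy 1.00, B-factor 0.00) so toy and
#' simulated structures round-trip through [read_structure()].
#'
#' @param structure atom tibble as returned by [read_structure()].
#' @param path optional file path; if `NULL` the text is returned invisibly.
#' @return character vector of PDB lines, invisibly when written to file.
#' @export
write_structure_pdb <- function(structure, path = NULL) {
  n <- nrow(structure)
  name4 <- ifelse(nchar(structure$elety) < 4,
                  sprintf(" %-3s", structure$elety),
                  substr(structure$elety, 1, 4))
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n) %% 100000L, name4, structure$resid, structure$chain,
    structure$resno, ifelse(structure$icode == "", " ", structure$icode),
    structure$x, structure$y, structure$z, structure$element
  )
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' List distinct residues of a chain in file order
#'
#' @param structure atom tibble.
#' @param chain chain identifier.
#' @return tibble with `chain`, `resno`, `icode`, `resid`, one row per residue.
#' @export
chain_residues <- function(structure, chain) {
  if (!chain %in% structure$chain) {
    abort(sprintf("chain '%s' not present in structure", chain))
  }
  structure |>
    filter(.data$chain == !!chain) |>
    distinct(.data$chain, .data$resno, .data$icode, .data$resid)
}
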