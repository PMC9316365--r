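#' Annotate ground-truth interface residues by inter-chain atomic contact
#'
#' A residue of the query chain is labelled interfacial (1) when at least
#' one of its heavy atoms lies within `cutoff` Angstrom of any heavy atom
#' of any partner chain, the standard 4.0 A contact rule for deriving
#' interface annotations from a complex structure. Hydrogens are ignored:
#' most depositions lack them and the 4.0 A criterion is a heavy-atom
#' convention.
#'
#' @param structure atom tibble of the complex (see [read_structure()]).
#' @param query_chain chain whose residues are annotated.
#' @param partner_chains character vector of partner chain ids.
#' @param cutoff contact distance in Angstrom (default 4.0).
#' @param protein_id optional identifier carried into the output.
#' @param contact_filter optional function `(query_atoms, partner_atoms,
#'   distances) -> logical` applied to candidate contacts, a hook for
#'   stricter contact-legitimacy schemes; `NULL` keeps the pure distance
#'   criterion.
#' @return tibble with `protein_id`, `chain`, `resno`, `icode`, `resid`,
#'   `label` (integer 0/1), one row per query-chain residue in file order;
#'   the cutoff is stored in attribute `"cutoff"`.
#' @export
annotate_interface <- function(structure, query_chain, partner_chains,
                               cutoff = 4.0, protein_id = NA_character_,
                               contact_filter = NULL) {
  if (cutoff <= 0) abort("`cutoff` must be positive")
  chains <- unique(structure$chain)
  missing <- setdiff(c(query_chain, partner_chains), chains)
  if (length(missing) > 0) {
    abort(sprintf("chain(s) not present in structure: %s",
                  paste(missing, collapse = ", ")))
  }
  if (query_chain %in% partner_chains) {
    abort("query chain cannot be one of the partner chains")
  }

  heavy <- structure |> filter(.data$element != "H")
  q <- heavy |> filter(.data$chain == query_chain)
  p <- heavy |> filter(.data$chain %in% partner_chains)
  if (nrow(q) == 0) abort("query chain has no heavy atoms")

  residues <- chain_residues(structure, query_chain)
  qkey <- residue_key(q$chain, q$resno, q$icode)

  contact <- rep(FALSE, nrow(q))
  if (nrow(p) > 0) {
    qm <- as.matrix(q[, c("x", "y", "z")])
    pm <- as.matrix(p[, c("x", "y", "z")])
    # squared-distance matrix in blocks to bound memory on large complexes
    block <- max(1L, floor(4e6 / nrow(p)))
    cut2 <- cutoff^2
    for (start in seq(1L, nrow(qm), by = block)) {
      idx <- start:min(start + block - 1L, nrow(qm))
      d2 <- outer(rowSums(qm[idx, , drop = FALSE]^2), rowSums(pm^2), "+") -
        2 * tcrossprod(qm[idx, , drop = FALSE], pm)
      hit <- d2 <= cut2
      if (!is.null(contact_filter)) {
        hit <- hit & contact_filter(q[idx, , drop = FALSE], p, sqrt(pmax(d2, 0)))
      }
      contact[idx] <- rowSums(hit) > 0
    }
  }

  labelled_keys <- unique(qkey[contact])
  out <- residues |>
    mutate(
      protein_id = protein_id,
      label = as.integer(residue_key(.data$chain, .data$resno, .data$icode)
                         %in% labelled_keys)
    ) |>
    select("protein_id", "chain", "resno", "icode", "resid", "label")
  attr(out, "cutoff") <- cutoff
  out
}

#' Interface residue set of a single docked pose
#'
#' Thin wrapper over [annotate_interface()] returning the residue keys of
#' the query chain in contact with the docked partner, the per-pose
#' primitive of the docking-frequency score.
#'
#' @inheritParams annotate_interface
#' @param partner_chain single partner chain id.
#' @return character vector of residue keys (`chain:resno:icode`).
#' @export
pose_interface_set <- function(structure, query_chain, partner_chain,
                               cutoff = 4.0) {
  ann <- annotate_interface(structure, query_chain, partner_chain,
                            cutoff = cutoff)
  with(ann[ann$label == 1L, ], residue_key(chain, resno, icode))
}
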