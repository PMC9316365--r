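#' Docking-pose interface-frequency scores
#'
#' The docking-based per-residue interface likelihood: for every query
#' residue, the fraction of docked poses in which it sits at the pose
#' interface, averaged over the non-cognate binding partners. With the
#' default equal-weight mode, `score(r) = (1/P) * sum_partners
#' (poses with r interfacial / poses of that partner)`; `pooled = TRUE`
#' instead pools all poses into one denominator (the two coincide when
#' every partner contributes the same number of poses).
#'
#' @param interfaces tibble of per-pose interface membership with columns
#'   `partner_id`, `pose_id`, `chain`, `resno`, `icode` — one row per
#'   (pose, interfacial residue). Poses with an empty interface need not
#'   appear when `pose_counts` is supplied.
#' @param query_residues tibble with `chain`, `resno`, `icode` (file
#'   order preserved in the output), or a character vector of residue keys.
#' @param pose_counts tibble (`partner_id`, `n_poses`). When `NULL`, pose
#'   counts are inferred as the number of distinct `pose_id` per partner
#'   (which undercounts if contact-free poses were omitted).
#' @param pooled average per-partner fractions (`FALSE`, default) or pool
#'   every pose into a single fraction (`TRUE`).
#' @return tibble of `query_residues` plus a `dockpred` column in
#'   \[0, 1\]; attributes `"partners"` and `"pose_counts"`.
#' @export
dockpred_scores <- function(interfaces, query_residues, pose_counts = NULL,
                            pooled = FALSE) {
  if (is.character(query_residues)) {
    parts <- strsplit(query_residues, ":", fixed = TRUE)
    query_residues <- tibble(
      chain = purrr::map_chr(parts, 1),
      resno = as.integer(purrr::map_chr(parts, 2)),
      icode = purrr::map_chr(parts, ~ if (length(.x) >= 3) .x[3] else "")
    )
  }
  qkeys <- residue_key(query_residues$chain, query_residues$resno,
                       query_residues$icode)
  if (anyDuplicated(qkeys)) abort("duplicate query residues")

  if (is.null(pose_counts)) {
    pose_counts <- interfaces |>
      distinct(.data$partner_id, .data$pose_id) |>
      count(.data$partner_id, name = "n_poses")
  }
  if (nrow(pose_counts) == 0 || any(pose_counts$n_poses < 1)) {
    abort("every partner must contribute at least one pose")
  }

  ikeys <- residue_key(interfaces$chain, interfaces$resno, interfaces$icode)
  if (!all(ikeys %in% qkeys)) {
    abort(sprintf("interface residues not in the query set: %s",
                  paste(utils::head(setdiff(ikeys, qkeys), 3), collapse = ", ")))
  }
  if (!all(interfaces$partner_id %in% pose_counts$partner_id)) {
    abort("interface rows reference partners absent from `pose_counts`")
  }

  counts <- interfaces |>
    mutate(key = ikeys) |>
    distinct(.data$partner_id, .data$pose_id, .data$key) |>
    count(.data$partner_id, .data$key, name = "hits")

  if (pooled) {
    total <- sum(pose_counts$n_poses)
    per_res <- counts |>
      group_by(.data$key) |>
      summarise(score = sum(.data$hits) / total, .groups = "drop")
  } else {
    p <- nrow(pose_counts)
    per_res <- counts |>
      left_join(pose_counts, by = "partner_id") |>
      mutate(frac = .data$hits / .data$n_poses) |>
      group_by(.data$key) |>
      summarise(score = sum(.data$frac) / p, .groups = "drop")
  }

  score <- per_res$score[match(qkeys, per_res$key)]
  score[is.na(score)] <- 0
  out <- query_residues |> mutate(dockpred = score)
  attr(out, "partners") <- sort(unique(pose_counts$partner_id))
  attr(out, "pose_counts") <- pose_counts
  out
}

#' DockPred scores from docked-pose coordinate files
#'
#' Convenience front end that derives per-pose interface sets from full
#' coordinate poses (one structure per pose, query chain in a fixed frame
#' plus the partner chain docked) and aggregates them with
#' [dockpred_scores()].
#'
#' @param poses named list: one element per partner, each a list of atom
#'   tibbles (or PDB file paths) for that partner's poses.
#' @param query_chain,partner_chain chain ids inside each pose.
#' @param cutoff contact distance in Angstrom.
#' @inheritParams dockpred_scores
#' @return as [dockpred_scores()].
#' @export
dockpred_from_poses <- function(poses, query_chain, partner_chain,
                                cutoff = 4.0, pooled = FALSE) {
  if (length(poses) == 0) abort("at least one partner required")
  if (is.null(names(poses)) || any(names(poses) == "")) {
    abort("`poses` must be a named list (partner ids as names)")
  }
  query_residues <- NULL
  rows <- purrr::imap(poses, function(partner_poses, pid) {
    if (length(partner_poses) == 0) abort("partner with zero poses")
    purrr::imap(partner_poses, function(pose, i) {
      st <- if (is.character(pose)) read_structure(pose) else pose
      res <- chain_residues(st, query_chain)
      if (is.null(query_residues)) {
        query_residues <<- res
      } else if (!identical(res, query_residues)) {
        abort("query residue set differs across poses")
      }
      ann <- annotate_interface(st, query_chain, partner_chain, cutoff = cutoff)
      ann |>
        filter(.data$label == 1L) |>
        transmute(partner_id = pid, pose_id = i,
                  chain = .data$chain, resno = .data$resno,
                  icode = .data$icode)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  pose_counts <- tibble(partner_id = names(poses),
                        n_poses = lengths(poses))
  dockpred_scores(rows, query_residues, pose_counts = pose_counts,
                  pooled = pooled)
}
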