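#' Label-conditional Beta score channel
#'
#' Convenience constructor for the synthetic generator's per-predictor
#' score model: interfacial residues draw from `Beta(2 + 2*signal, 2)`,
#' non-interfacial from `Beta(2, 2 + 2*signal)`, so `signal = 0` is an
#' uninformative channel and `signal = 1` the "moderate" default
#' (Beta(4, 2) vs Beta(2, 4)); larger signal separates the classes
#' further (stochastic dominance of the positive-class distribution).
#'
#' @param signal non-negative separation strength.
#' @return list with `pos` and `neg` Beta shape pairs.
#' @export
beta_channel <- function(signal = 1) {
  if (signal < 0) abort("`signal` must be non-negative")
  list(pos = c(2 + 2 * signal, 2), neg = c(2, 2 + 2 * signal))
}

default_channels <- function() {
  list(template_based = beta_channel(1),
       template_free = beta_channel(1),
       docking = beta_channel(1))
}

#' Simulate a per-residue predictor score table
#'
#' Generates labelled score tables with the statistical structure the
#' integrator assumes: proteins of 50-450 residues, a small Beta-
#' distributed interfacial fraction per protein (mean 0.12), and several
#' bounded score channels whose class separation, mutual correlation and
#' per-protein failure rate are controllable. Channel scores come from
#' label-conditional Beta distributions coupled through a Gaussian-copula
#' shared latent factor (`rho = 0`: orthogonal channels; `rho -> 1`:
#' redundant channels). A "failed" (protein, channel) pair draws its
#' scores against a relabelling of the protein's residues, so its
#' marginal looks normal but carries no information. The surface count
#' `R` is set to a fixed fraction of the residue count, since simulated
#' proteins have no geometry.
#'
#' @param n_proteins number of proteins.
#' @param len_range inclusive residue-count range (uniform).
#' @param interface_mean mean per-protein interfacial fraction.
#' @param interface_conc Beta concentration of that fraction (a + b).
#' @param channels named list of score channels (see [beta_channel()]).
#' @param rho shared-latent correlation between channels, in \[0, 1).
#' @param failure_prob chance a given channel fails on a given protein.
#' @param failure_channels channels eligible to fail (default all).
#' @param surface_fraction `R / length` for every protein.
#' @param seed RNG seed; output is reproducible given the seed.
#' @param id_prefix protein id prefix.
#' @return labelled score tibble: `protein_id`, `chain`, `resno`,
#'   `icode`, one column per channel, `label`, `R`; attribute
#'   `"failures"` records the failed (protein, channel) pairs.
#' @export
simulate_scores <- function(n_proteins = 100,
                            len_range = c(50, 450),
                            interface_mean = 0.12,
                            interface_conc = 30,
                            channels = default_channels(),
                            rho = 0,
                            failure_prob = 0,
                            failure_channels = names(channels),
                            surface_fraction = 0.7,
                            seed = 0,
                            id_prefix = "prot") {
  if (rho < 0 || rho >= 1) abort("`rho` must be in [0, 1)")
  if (interface_mean <= 0 || interface_mean >= 1) {
    abort("`interface_mean` must be in (0, 1)")
  }
  a0 <- interface_mean * interface_conc
  b0 <- (1 - interface_mean) * interface_conc
  if (a0 <= 0 || b0 <= 0) abort("infeasible interface Beta parameters")
  for (ch in channels) {
    if (any(c(ch$pos, ch$neg) <= 0)) abort("infeasible channel Beta parameters")
  }
  ch_names <- names(channels)

  with_substream(seed, "simulate", {
    failures <- list()
    tabs <- purrr::map(seq_len(n_proteins), function(i) {
      pid <- sprintf("%s%03d", id_prefix, i)
      len <- sample(seq(len_range[1], len_range[2]), 1)
      frac <- stats::rbeta(1, a0, b0)
      label <- stats::rbinom(len, 1, frac)
      # guarantee both classes so per-protein metrics are defined
      if (sum(label) == 0) label[sample.int(len, 1)] <- 1L
      if (sum(label) == len) label[sample.int(len, 1)] <- 0L

      # Gaussian copula: one shared factor per residue + channel noise
      z0 <- stats::rnorm(len)
      failed <- ch_names %in% failure_channels &
        stats::runif(length(ch_names)) < failure_prob
      scores <- purrr::imap(channels, function(ch, nm) {
        z <- sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(len)
        u <- stats::pnorm(z)
        eff_label <- if (failed[match(nm, ch_names)]) sample(label) else label
        ifelse(eff_label == 1L,
               stats::qbeta(u, ch$pos[1], ch$pos[2]),
               stats::qbeta(u, ch$neg[1], ch$neg[2]))
      })
      if (any(failed)) {
        failures[[pid]] <<- ch_names[failed]
      }
      tibble(protein_id = pid, chain = "A", resno = seq_len(len),
             icode = "", !!!scores, label = as.integer(label),
             R = as.integer(round_half_up(surface_fraction * len)))
    })
    out <- purrr::list_rbind(tabs)
    attr(out, "failures") <- failures
    attr(out, "channels") <- ch_names
    out
  })
}

#' Build a toy two-chain complex with a known interface
#'
#' Places the query chain as C-alpha pseudo-atoms on a straight line at
#' 8 A spacing and, for each designated interface residue, one partner
#' pseudo-atom 3.4 A away; every other partner atom sits more than 6 A
#' from every query atom. With margins 3.4 vs > 6 A around the 4.0 A
#' contact rule, [annotate_interface()] must recover exactly the
#' designated residues.
#'
#' @param n_query query-chain residues.
#' @param n_interface number of designated interface residues.
#' @param seed RNG seed (picks which residues are interfacial).
#' @return list with `structure` (atom tibble, chains A = query,
#'   B = partner) and `labels` (tibble `chain`, `resno`, `icode`,
#'   `label`).
#' @export
generate_toy_complex <- function(n_query, n_interface, seed = 0) {
  if (n_interface > n_query) abort("more interface residues than residues")
  if (n_query < 1) abort("need at least one query residue")
  picked <- with_substream(seed, "toy_complex",
                           sort(sample.int(n_query, n_interface)))
  qx <- 8 * (seq_len(n_query) - 1)
  query <- tibble(chain = "A", resno = seq_len(n_query), icode = "",
                  resid = "GLY", elety = "CA", element = "C",
                  x = qx, y = 0, z = 0, occ = 1)
  partner_near <- tibble(chain = "B",
                         resno = seq_along(picked),
                         icode = "", resid = "GLY", elety = "CA",
                         element = "C",
                         x = qx[picked], y = 3.4, z = 0, occ = 1)
  # distant partner atoms so the partner chain is never empty
  partner_far <- tibble(chain = "B",
                        resno = length(picked) + 1:2,
                        icode = "", resid = "GLY", elety = "CA",
                        element = "C",
                        x = c(-30, 8 * n_query + 30), y = 50, z = 0, occ = 1)
  labels <- tibble(chain = "A", resno = seq_len(n_query), icode = "",
                   label = as.integer(seq_len(n_query) %in% picked))
  list(structure = dplyr::bind_rows(query, partner_near, partner_far),
       labels = labels)
}

#' Build an exact docking-pose fixture from target pose fractions
#'
#' Emits precomputed per-pose interface sets whose empirical frequencies
#' equal a prescribed schedule exactly: residue `i` of partner `j` with
#' scheduled fraction `f` appears in the first `f * n_poses` poses.
#'
#' @param schedule numeric matrix (residues x partners) of target pose
#'   fractions in \[0, 1\]; column names become partner ids.
#' @param n_poses poses per partner (scalar or per-partner vector);
#'   every `f * n_poses` must be an integer.
#' @return list with `interfaces` and `pose_counts` ready for
#'   [dockpred_scores()], plus `query_residues`.
#' @export
generate_pose_fixture <- function(schedule, n_poses = 2000) {
  if (any(schedule < 0 | schedule > 1)) abort("fractions must be in [0, 1]")
  n_res <- nrow(schedule)
  partners <- colnames(schedule) %||% sprintf("partner%02d", seq_len(ncol(schedule)))
  n_poses <- rep_len(n_poses, ncol(schedule))
  counts <- sweep(schedule, 2, n_poses, "*")
  if (any(abs(counts - round(counts)) > 1e-9)) {
    abort("every fraction * n_poses must be an integer")
  }
  counts <- round(counts)
  query_residues <- tibble(chain = "A", resno = seq_len(n_res), icode = "")
  rows <- purrr::map(seq_along(partners), function(j) {
    hit <- which(counts[, j] > 0)
    if (length(hit) == 0) return(NULL)
    purrr::map(hit, function(i) {
      tibble(partner_id = partners[j],
             pose_id = seq_len(counts[i, j]),
             chain = "A", resno = i, icode = "")
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (is.null(rows)) {
    rows <- tibble(partner_id = character(), pose_id = integer(),
                   chain = character(), resno = integer(),
                   icode = character())
  }
  list(interfaces = rows,
       pose_counts = tibble(partner_id = partners, n_poses = n_poses),
       query_residues = query_residues)
}
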