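# Squared-distance matrix between two coordinate matrices (rows = atoms).
cross_dist2 <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(Y))) +
    outer(rep(1, nrow(X)), rowSums(Y^2)) - 2 * X %*% t(Y)
  d2[d2 < 0] <- 0
  d2
}

# One frame's coordinates of selected atoms, always as an n x 3 matrix.
frame_coords <- function(traj, idx, f) {
  matrix(traj$coords[idx, , f], ncol = 3L)
}

atom_rows <- function(traj, chain, resids, heavy_only = TRUE) {
  at <- traj$atoms
  keep <- at$chain == chain & at$resid %in% resids
  if (heavy_only) keep <- keep & at$element != "H"
  which(keep)
}

#' Minimum inter-motif distance time series
#'
#' Per frame, the minimum heavy-atom distance between the residues of
#' `motif_a_span` on chain A and `motif_b_span` on chain B, the observable
#' by which N- and C-pose dimer contacts are monitored.
#'
#' @param traj A `helix_dimer_trajectory`.
#' @param motif_a_span,motif_b_span Residue-number vectors (default: the
#'   trajectory's annotated TGMVGA span on both chains).
#' @return Numeric vector (nm), one value per frame.
#' @export
min_motif_distance <- function(traj,
                               motif_a_span = traj$motifs$tgmvga,
                               motif_b_span = traj$motifs$tgmvga) {
  stopifnot(inherits(traj, "helix_dimer_trajectory"))
  ia <- atom_rows(traj, "A", motif_a_span)
  ib <- atom_rows(traj, "B", motif_b_span)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("motif span maps to no atoms on chain ",
         if (length(ia) == 0L) "A" else "B")
  }
  vapply(seq_len(n_frames(traj)), function(f) {
    sqrt(min(cross_dist2(frame_coords(traj, ia, f),
                         frame_coords(traj, ib, f))))
  }, numeric(1L))
}

#' Averaged residue-residue contact-distance map
#'
#' Entry (i, j) is the mean over frames of the per-frame minimum distance
#' between residue i of chain A and residue j of chain B. The contact
#' distance is the minimum heavy-atom distance by default; `method = "ca"`
#' uses Calpha-Calpha distances instead.
#'
#' @param traj A `helix_dimer_trajectory`.
#' @param method `"heavy"` (default) or `"ca"`.
#' @return A matrix (nm) of class `contact_map`, rows = chain A residues,
#'   columns = chain B residues (dimnames carry residue numbers).
#' @export
contact_distance_map <- function(traj, method = c("heavy", "ca")) {
  stopifnot(inherits(traj, "helix_dimer_trajectory"), n_frames(traj) >= 1L)
  method <- match.arg(method)
  at <- traj$atoms
  sel <- if (method == "ca") at$atom == "CA" else at$element != "H"
  ia <- which(at$chain == "A" & sel)
  ib <- which(at$chain == "B" & sel)
  res_a <- sort(unique(at$resid[ia]))
  res_b <- sort(unique(at$resid[ib]))
  ga <- match(at$resid[ia], res_a)
  gb <- match(at$resid[ib], res_b)
  acc <- matrix(0, length(res_a), length(res_b),
                dimnames = list(res_a, res_b))
  cols_b <- split(seq_along(ib), gb)
  rows_a <- split(seq_along(ia), ga)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    d <- sqrt(cross_dist2(frame_coords(traj, ia, f),
                          frame_coords(traj, ib, f)))
    # atoms x residues_b, then residues_a x residues_b, by group minima
    d_b <- vapply(cols_b, function(j)
      apply(d[, j, drop = FALSE], 1L, min), numeric(length(ia)))
    per_res <- t(vapply(rows_a, function(i)
      apply(d_b[i, , drop = FALSE], 2L, min), numeric(length(res_b))))
    acc <- acc + per_res
  }
  out <- acc / nf
  class(out) <- c("contact_map", class(out))
  out
}

#' Hydrogen-bond geometric criterion
#'
#' Without explicit hydrogens (the default for heavy-atom fixtures): a bond
#' requires donor-acceptor distance at or below `dist_cutoff` and the
#' acceptor to lie within `cone_deg` of the antecedent-to-donor direction
#' (where the hydrogen would roughly sit). With hydrogens, the
#' donor-hydrogen-acceptor angle must be at least `dha_deg`.
#'
#' @param dist_cutoff Donor-acceptor distance cutoff, nm (default 0.35).
#' @param cone_deg Acceptor-donor-antecedent cone, degrees (default 30).
#' @param dha_deg Donor-hydrogen-acceptor angle cutoff, degrees (default
#'   150), used only when a hydrogen atom is supplied.
#' @return A list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(dist_cutoff = 0.35, cone_deg = 30,
                            dha_deg = 150) {
  stopifnot(dist_cutoff > 0, cone_deg > 0, dha_deg > 0)
  structure(list(dist_cutoff = dist_cutoff, cone_deg = cone_deg,
                 dha_deg = dha_deg),
            class = "hbond_criterion")
}

angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

single_atom_row <- function(traj, chain, resid, atom) {
  i <- which(traj$atoms$chain == chain & traj$atoms$resid == resid &
               traj$atoms$atom == atom)
  if (length(i) != 1L) {
    stop(sprintf("atom %s of residue %d on chain %s: found %d (expected 1)",
                 atom, resid, chain, length(i)))
  }
  i
}

#' Gln-Gln hydrogen-bond occupancy
#'
#' Fraction of frames in which the side-chain donor of the named residue on
#' one chain is hydrogen-bonded to the acceptor of the residue on the other
#' chain, in either direction (A donates to B or B to A; a frame counts
#' once). Defaults are the Gln side-chain amide atoms (donor NE2 with
#' antecedent CD, acceptor OE1).
#'
#' @param traj A `helix_dimer_trajectory`.
#' @param donor_residue,acceptor_residue Residue numbers (default 658 on
#'   both chains, the Gln of the transmembrane variant).
#' @param criterion A [hbond_criterion()].
#' @param donor_atom,acceptor_atom,antecedent_atom Atom names.
#' @param hydrogen_atom Optional hydrogen atom name; if present in the
#'   topology, the donor-hydrogen-acceptor angle test is used instead of the
#'   cone.
#' @return Occupancy in \[0, 1\].
#' @export
hbond_occupancy <- function(traj, donor_residue = 658L,
                            acceptor_residue = 658L,
                            criterion = hbond_criterion(),
                            donor_atom = "NE2", acceptor_atom = "OE1",
                            antecedent_atom = "CD", hydrogen_atom = NULL) {
  stopifnot(inherits(traj, "helix_dimer_trajectory"),
            inherits(criterion, "hbond_criterion"))
  idx <- list(
    AtoB = list(
      d = single_atom_row(traj, "A", donor_residue, donor_atom),
      ant = single_atom_row(traj, "A", donor_residue, antecedent_atom),
      a = single_atom_row(traj, "B", acceptor_residue, acceptor_atom),
      h = if (!is.null(hydrogen_atom))
        single_atom_row(traj, "A", donor_residue, hydrogen_atom)
    ),
    BtoA = list(
      d = single_atom_row(traj, "B", donor_residue, donor_atom),
      ant = single_atom_row(traj, "B", donor_residue, antecedent_atom),
      a = single_atom_row(traj, "A", acceptor_residue, acceptor_atom),
      h = if (!is.null(hydrogen_atom))
        single_atom_row(traj, "B", donor_residue, hydrogen_atom)
    )
  )
  bonded_direction <- function(f, ix) {
    D <- traj$coords[ix$d, , f]
    A <- traj$coords[ix$a, , f]
    if (sqrt(sum((A - D)^2)) > criterion$dist_cutoff) return(FALSE)
    if (!is.null(ix$h)) {
      H <- traj$coords[ix$h, , f]
      return(angle_deg(D - H, A - H) >= criterion$dha_deg)
    }
    ant <- traj$coords[ix$ant, , f]
    angle_deg(D - ant, A - D) <= criterion$cone_deg
  }
  mean(vapply(seq_len(n_frames(traj)), function(f) {
    bonded_direction(f, idx$AtoB) || bonded_direction(f, idx$BtoA)
  }, logical(1L)))
}

#' Write a per-frame series or a contact map as TSV
#'
#' @param x Numeric vector (series) or `contact_map` matrix.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_traj_observable <- function(x, path) {
  if (inherits(x, "contact_map")) {
    df <- data.frame(residue_a = rep(rownames(x), ncol(x)),
                     residue_b = rep(colnames(x), each = nrow(x)),
                     mean_min_distance_nm = as.vector(x))
  } else {
    df <- data.frame(frame = seq_along(x), value_nm = as.numeric(x))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
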