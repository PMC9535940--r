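#' Write a trajectory as a multi-MODEL PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame, chains as stored (A/B), coordinates
#' converted from nm to Angstrom. Fixed-column ATOM records at standard PDB
#' precision (0.001 A).
#'
#' @param traj A `helix_dimer_trajectory`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_dimer_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "helix_dimer_trajectory"))
  at <- traj$atoms
  nf <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$coords[, , f] * 10  # nm -> Angstrom
    lines <- sprintf(
      "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)), at$atom, at$resname, at$chain, at$resid,
      xyz[, 1L], xyz[, 2L], xyz[, 3L], at$element)
    writeLines(lines, con)
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-MODEL PDB file as a trajectory
#'
#' Minimal fixed-column reader for ATOM/HETATM records; coordinates are
#' converted from Angstrom to nm on ingest. All models must share the same
#' atom topology. Chains are identified by the PDB chain ID; if motif spans
#' are not supplied, the packaged defaults (TGMVGA 648-653, ALGIG 661-665)
#' are attached.
#'
#' @param path File path.
#' @param motifs Optional named list of residue-number spans.
#' @return A `helix_dimer_trajectory`.
#' @export
read_dimer_pdb <- function(path, motifs = list(tgmvga = TGMVGA_SPAN,
                                               algig = ALGIG_SPAN)) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0L) {
    frame_of <- rep(1L, sum(is_atom))
  } else {
    frame_id <- cumsum(startsWith(lines, "MODEL"))
    frame_of <- frame_id[is_atom]
  }
  al <- lines[is_atom]
  if (length(al) == 0L) stop("no ATOM records in ", path)
  parse_block <- function(v) {
    data.frame(
      atom = trimws(substr(v, 13L, 16L)),
      resname = trimws(substr(v, 18L, 20L)),
      chain = trimws(substr(v, 22L, 22L)),
      resid = as.integer(substr(v, 23L, 26L)),
      x = as.numeric(substr(v, 31L, 38L)) / 10,
      y = as.numeric(substr(v, 39L, 46L)) / 10,
      z = as.numeric(substr(v, 47L, 54L)) / 10,
      element = trimws(substr(v, 77L, 78L)),
      stringsAsFactors = FALSE
    )
  }
  nf <- max(frame_of)
  per_frame <- split(al, frame_of)
  first <- parse_block(per_frame[[1L]])
  natoms <- nrow(first)
  coords <- array(NA_real_, c(natoms, 3L, nf))
  for (f in seq_len(nf)) {
    blk <- parse_block(per_frame[[f]])
    if (nrow(blk) != natoms ||
        !identical(blk[c("atom", "chain", "resid")],
                   first[c("atom", "chain", "resid")])) {
      stop("model ", f, " does not match the topology of model 1")
    }
    coords[, , f] <- as.matrix(blk[c("x", "y", "z")])
  }
  atoms <- first[c("chain", "resid", "resname", "atom", "element")]
  atoms$element[atoms$element == ""] <- substr(atoms$atom[atoms$element == ""],
                                               1L, 1L)
  structure(
    list(atoms = atoms, coords = coords, motifs = motifs,
         pose = NA_character_, variant = NULL,
         hbond_frames = rep(NA, nf)),
    class = "helix_dimer_trajectory"
  )
}
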