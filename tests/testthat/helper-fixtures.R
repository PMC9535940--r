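# Shared fixtures and independent oracles, built in code at test time.

# Independent translation oracle: mutate the full nucleotide string and
# translate it with Biostrings (a different code path than the per-codon
# lookup used by the implementation).
oracle_translate_variant <- function(cds, nt_pos, alt) {
  s <- cds$nucleotides
  substr(s, nt_pos, nt_pos) <- alt
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     no.init.codon = TRUE))
}

# Brute-force SNV enumeration oracle.
oracle_enumerate <- function(cds) {
  bases <- c("A", "C", "G", "T")
  ref <- strsplit(cds$nucleotides, "")[[1]]
  out <- list()
  for (p in seq_along(ref)) {
    for (b in setdiff(bases, ref[p])) {
      out[[length(out) + 1]] <- data.frame(nt_pos = p, ref = ref[p], alt = b)
    }
  }
  do.call(rbind, out)
}

# Hand-built count table: three variants, two conditions, explicit coverage.
toy_count_table <- function() {
  variants <- data.frame(
    nt_pos = c(10L, 11L, 20L), ref = c("C", "A", "G"), alt = c("T", "G", "A"),
    protein_change = c("A4V", "A4D", "G7R"),
    stringsAsFactors = FALSE
  )
  counts <- cbind(act = c(150L, 0L, 1200L), lof = c(5L, 3L, 900L))
  coverage <- matrix(c(10000L, 10000L, 10000L, 10000L, 10000L, 10000L),
                     nrow = 3, dimnames = list(c("10", "11", "20"),
                                               c("act", "lof")))
  variant_count_table(variants, counts, coverage)
}

# Minimal hand-placed two-chain trajectory for exhaustive-oracle checks.
# Two residues per chain, two atoms each, coordinates chosen by hand.
toy_trajectory <- function(coords_by_frame) {
  atoms <- data.frame(
    chain = rep(c("A", "B"), each = 4),
    resid = rep(c(1L, 1L, 2L, 2L), 2),
    resname = "GLY",
    atom = rep(c("CA", "C"), 4),
    element = rep(c("C", "C"), 4),
    stringsAsFactors = FALSE
  )
  nf <- length(coords_by_frame)
  coords <- array(NA_real_, c(8, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- coords_by_frame[[f]]
  structure(list(atoms = atoms, coords = coords,
                 motifs = list(tgmvga = 1L, algig = 2L),
                 pose = NA_character_, variant = NULL,
                 hbond_frames = rep(NA, nf)),
            class = "helix_dimer_trajectory")
}

# Brute-force minimum distance between two atom index sets, one frame.
oracle_min_dist <- function(traj, ia, ib, f) {
  best <- Inf
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((traj$coords[i, , f] - traj$coords[j, , f])^2))
    best <- min(best, d)
  }
  best
}

# Rigid-body transform applied to every frame of a trajectory.
transform_trajectory <- function(traj, angle = 0.7, shift = c(1, -2, 3)) {
  R <- rbind(c(cos(angle), -sin(angle), 0),
             c(sin(angle),  cos(angle), 0),
             c(0, 0, 1))
  for (f in seq_len(dim(traj$coords)[3])) {
    traj$coords[, , f] <- sweep(traj$coords[, , f] %*% t(R), 2, shift, "+")
  }
  traj
}
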