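AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# Default motif annotation of the dimer segment, precursor numbering:
# N-terminal double small-x-x-x-small motif and C-terminal single motif.
TGMVGA_SPAN <- 648:653
ALGIG_SPAN <- 661:665

#' Simulate an idealized transmembrane helix-dimer trajectory
#'
#' Builds multi-frame coordinates of two 30-residue ideal alpha-helices
#' (rise 0.15 nm/residue, 100 deg/residue, heavy atoms: backbone N/CA/C/O,
#' CB, and a full Gln side chain where present) arranged as a crossing dimer.
#' In the N-pose the TGMVGA motifs (residues 648-653) face each other at the
#' crossing point; in the C-pose the ALGIG motifs (661-665) do. Chain B is
#' the exact two-fold image of chain A about the dimer axis, so contact maps
#' are chain-swap symmetric by construction. Per-frame Gaussian jitter is
#' applied (mirrored onto chain B). In a stated fraction of frames
#' (`round(hbond_fraction * n_frames)`, the leading frames), the Gln-658
#' side-chain donor/acceptor atoms of the `"L658Q"` variant are placed at the
#' interface so the geometric hydrogen-bond criterion is met; in all other
#' frames they point away from the interface. This is a geometric fixture,
#' not a physical simulation: side-chain internal geometry is not realistic.
#'
#' @param pose `"N"` or `"C"`.
#' @param n_frames Number of frames (>= 1).
#' @param hbond_fraction Fraction of frames with the Gln-Gln hydrogen bond
#'   in \[0, 1\]; requires `variant = "L658Q"` if > 0.
#' @param variant `"wt"`, `"L658Q"` or `"G652R"` applied to the K642-R671
#'   segment.
#' @param seed Optional integer seed for the jitter.
#' @param jitter_sd Per-coordinate jitter SD in nm (0 gives the exactly
#'   symmetric, noise-free fixture).
#' @param axis_separation Axis-to-axis distance at the crossing point (nm).
#' @param splay Tangent of the half crossing angle; controls how fast the
#'   helices separate away from the contact point.
#' @return A `helix_dimer_trajectory`: list with `atoms` (data.frame
#'   `chain`, `resid`, `resname`, `atom`, `element`), `coords` (array
#'   natoms x 3 x n_frames, nm), `motifs`, `pose`, `hbond_frames`.
#' @export
simulate_helix_dimer <- function(pose = c("N", "C"), n_frames = 100L,
                                 hbond_fraction = 0,
                                 variant = c("wt", "L658Q", "G652R"),
                                 seed = NULL, jitter_sd = 0.01,
                                 axis_separation = 1.21, splay = 0.45) {
  pose <- match.arg(pose)
  variant <- match.arg(variant)
  if (hbond_fraction < 0 || hbond_fraction > 1) {
    stop("hbond_fraction must be in [0, 1]")
  }
  stopifnot(n_frames >= 1, jitter_sd >= 0)
  seq1 <- strsplit(unclass(egfr_tm_sequence("dimer")), "")[[1L]]
  offset <- attr(egfr_tm_sequence("dimer"), "offset")
  resids <- seq_along(seq1) + offset - 1L
  if (variant == "L658Q") seq1[resids == 658L] <- "Q"
  if (variant == "G652R") seq1[resids == 652L] <- "R"
  if (hbond_fraction > 0 && !any(seq1 == "Q" & resids == 658L)) {
    stop("hbond_fraction > 0 requires variant = \"L658Q\" (Gln at 658)")
  }
  if (!is.null(seed)) set.seed(seed)

  rise <- 0.15; twist <- 100 * pi / 180; r_ca <- 0.23
  # contact centered on a side-chain-bearing residue near the motif midpoint
  # (M650 for the N-pose, I664 for the C-pose), so facing CB atoms realize
  # the sub-0.6 nm inter-motif contact
  i_center <- switch(pose, N = 650, C = 664) - offset
  z0 <- rise * i_center
  tilt <- atan(splay)

  # one residue's heavy atoms in the local (radial, tangential, z) frame
  atom_offsets <- function(aa) {
    off <- rbind(
      N  = c(-0.05, -0.08, -0.10),
      CA = c( 0.00,  0.00,  0.00),
      C  = c(-0.04,  0.09,  0.08),
      O  = c(-0.02,  0.12,  0.20)
    )
    if (aa != "G") off <- rbind(off, CB = c(0.152, 0.00, 0.03))
    if (aa == "Q") {
      off <- rbind(off,
                   CG  = c(0.28,  0.00, 0.06),
                   CD  = c(0.40,  0.00, 0.09),
                   OE1 = c(0.47,  0.06, 0.09),
                   NE2 = c(0.49, -0.07, 0.12))
    }
    off
  }

  atoms <- do.call(rbind, lapply(seq_along(seq1), function(i) {
    nm <- rownames(atom_offsets(seq1[i]))
    data.frame(chain = "A", resid = resids[i], resname = AA_THREE[[seq1[i]]],
               atom = nm, element = substr(nm, 1L, 1L),
               stringsAsFactors = FALSE)
  }))
  n_chain <- nrow(atoms)
  atoms <- rbind(atoms, transform(atoms, chain = "B"))
  rownames(atoms) <- NULL

  base_chain <- function() {
    coords <- matrix(NA_real_, n_chain, 3L)
    row <- 0L
    for (i in seq_along(seq1)) {
      theta <- pi + (i - 1L - i_center) * twist     # contact face at 180 deg
      off <- atom_offsets(seq1[i])
      # Gln side chain points outward (azimuth 0) unless an H-bond frame
      # repositions it; backbone/CB use the helical azimuth.
      for (a in seq_len(nrow(off))) {
        row <- row + 1L
        th <- if (rownames(off)[a] %in% c("CG", "CD", "OE1", "NE2")) 0 else theta
        r_hat <- c(cos(th), sin(th), 0)
        t_hat <- c(-sin(th), cos(th), 0)
        ca_r <- if (rownames(off)[a] %in% c("CG", "CD", "OE1", "NE2")) {
          c(cos(th), sin(th), 0) * r_ca
        } else r_hat * r_ca
        coords[row, ] <- ca_r + off[a, 1L] * r_hat + off[a, 2L] * t_hat +
          c(0, 0, rise * (i - 1L) + off[a, 3L])
      }
    }
    coords
  }
  template <- base_chain()

  rot_tilt <- rbind(c(1, 0, 0),
                    c(0, cos(tilt), -sin(tilt)),
                    c(0, sin(tilt),  cos(tilt)))
  transform_A <- function(xyz) {
    centered <- sweep(xyz, 2L, c(0, 0, z0))
    out <- centered %*% t(rot_tilt)
    sweep(out, 2L, c(axis_separation / 2, 0, z0), "+")
  }
  mirror <- function(xyz) {  # two-fold rotation about the global z axis
    xyz[, 1L] <- -xyz[, 1L]
    xyz[, 2L] <- -xyz[, 2L]
    xyz
  }

  n_hb <- round(hbond_fraction * n_frames)
  hbond_frames <- seq_len(n_frames) <= n_hb
  gln_sc <- which(atoms$chain == "A" & atoms$resid == 658L &
                    atoms$atom %in% c("CG", "CD", "OE1", "NE2"))
  gln_cb <- which(atoms$chain == "A" & atoms$resid == 658L &
                    atoms$atom == "CB")

  coords <- array(NA_real_, c(nrow(atoms), 3L, n_frames))
  for (f in seq_len(n_frames)) {
    xyz <- template
    if (jitter_sd > 0) {
      xyz <- xyz + matrix(rnorm(length(xyz), 0, jitter_sd), nrow(xyz))
    }
    xyz <- transform_A(xyz)
    if (hbond_frames[f]) {
      zs <- xyz[gln_cb, 3L]
      dir <- c(0.28, 0, 0.05); dir <- dir / sqrt(sum(dir^2))
      ne2 <- c(-0.30, 0, zs)
      oe1_partner <- ne2 + 0.284 * dir        # acceptor on the image chain
      oe1 <- c(-oe1_partner[1L], -oe1_partner[2L], oe1_partner[3L])
      cd <- ne2 - 0.133 * dir
      cg <- cd - 0.150 * dir
      xyz[gln_sc[match(c("CG", "CD", "OE1", "NE2"), atoms$atom[gln_sc])], ] <-
        rbind(cg, cd, oe1, ne2)
    }
    coords[seq_len(n_chain), , f] <- xyz
    coords[n_chain + seq_len(n_chain), , f] <- mirror(xyz)
  }

  structure(
    list(atoms = atoms, coords = coords,
         motifs = list(tgmvga = TGMVGA_SPAN, algig = ALGIG_SPAN),
         pose = pose, variant = variant, hbond_frames = hbond_frames),
    class = "helix_dimer_trajectory"
  )
}

#' @export
print.helix_dimer_trajectory <- function(x, ...) {
  cat(sprintf(
    "<helix_dimer_trajectory> %d frames, %d atoms/chain, pose %s (%s)\n",
    dim(x$coords)[3L], nrow(x$atoms) / 2L, x$pose,
    if (is.null(x$variant)) "file" else x$variant))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `helix_dimer_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]
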