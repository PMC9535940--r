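#' Kyte-Doolittle hydropathy scale
#'
#' The standard 20-entry hydropathy index; positive values are hydrophobic,
#' negative hydrophilic.
#'
#' @format Named numeric vector over the one-letter amino-acid alphabet.
#' @export
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Per-residue hydropathy profile
#'
#' Kyte-Doolittle values per residue, with an optional centered
#' sliding-window mean (odd window; edges where the window does not fit are
#' reported as `NA`).
#'
#' @param sequence Amino-acid string (standard alphabet).
#' @param numbering_offset Residue number of the first character.
#' @param window Odd window size (1 = raw per-residue values).
#' @return A data.frame of class `hydropathy_profile`: `position`,
#'   `residue`, `kd`, `window_mean`.
#' @export
kd_profile <- function(sequence, numbering_offset = 1L, window = 1L) {
  res <- strsplit(toupper(sequence), "")[[1L]]
  if (!all(res %in% names(KYTE_DOOLITTLE))) {
    stop("unknown residue letter(s): ",
         paste(unique(res[!res %in% names(KYTE_DOOLITTLE)]), collapse = ", "))
  }
  stopifnot(window >= 1L, window %% 2L == 1L)
  kd <- unname(KYTE_DOOLITTLE[res])
  n <- length(kd)
  wm <- rep(NA_real_, n)
  half <- (window - 1L) %/% 2L
  if (window <= n) {
    for (i in seq(1L + half, n - half)) {
      wm[i] <- mean(kd[(i - half):(i + half)])
    }
  }
  out <- data.frame(
    position = seq_len(n) + as.integer(numbering_offset) - 1L,
    residue = res, kd = kd, window_mean = wm,
    stringsAsFactors = FALSE
  )
  class(out) <- c("hydropathy_profile", "data.frame")
  out
}

#' Classify a residue as hydrophilic
#'
#' `TRUE` iff the residue's Kyte-Doolittle value is strictly below
#' `threshold`. The default threshold 0 is the conventional midpoint: it
#' labels Gln (-3.5) and Arg (-4.5) hydrophilic and all wild-type residues
#' of the transmembrane helix hydrophobic.
#'
#' @param residue One-letter residue code(s).
#' @param threshold Strict threshold (default 0).
#' @return Logical vector.
#' @export
classify_hydrophilic <- function(residue, threshold = 0) {
  residue <- toupper(residue)
  if (!all(residue %in% names(KYTE_DOOLITTLE))) {
    stop("unknown residue letter(s): ",
         paste(unique(residue[!residue %in% names(KYTE_DOOLITTLE)]),
               collapse = ", "))
  }
  unname(KYTE_DOOLITTLE[residue] < threshold)
}

#' Transmembrane annotation
#'
#' Inclusive helix boundaries plus the margin of the membrane-center rule: a
#' candidate position `p` must satisfy `p - tm_start > margin` and
#' `tm_end - p > margin` (strictly more than `margin` residues from either
#' end), excluding residues near the membrane surface whose hydrophilic side
#' chains could snorkel toward the lipid head groups.
#'
#' @param tm_start,tm_end Residue numbers (precursor numbering),
#'   `tm_start < tm_end`.
#' @param margin Non-negative integer, default 5.
#' @return A list of class `tm_annotation`.
#' @export
tm_annotation <- function(tm_start = 646L, tm_end = 668L, margin = 5L) {
  stopifnot(tm_start < tm_end, margin >= 0,
            tm_end - tm_start + 1L > 2L * margin)
  structure(list(tm_start = as.integer(tm_start), tm_end = as.integer(tm_end),
                 margin = as.integer(margin)),
            class = "tm_annotation")
}

#' Scan catalogue mutations for hydrophilic membrane-central candidates
#'
#' Reproduces the transmembrane candidate rule: keep substitutions whose
#' mutant residue is hydrophilic (Kyte-Doolittle below `threshold`) and
#' whose position lies strictly more than `margin` residues from both helix
#' ends. Positions outside the annotated sequence window (if one is given)
#' are skipped with a warning.
#'
#' @param mutations Data.frame with `protein_change` (e.g. `G652R`) or the
#'   triplet `wt_aa`, `position`, `mut_aa`; an `occurrence_count` column, if
#'   present, must be >= 1.
#' @param tm A [tm_annotation()].
#' @param threshold Hydrophilicity threshold, passed to
#'   [classify_hydrophilic()].
#' @param sequence_window Optional `c(first, last)` residue-number window of
#'   the annotated sequence.
#' @return The candidate rows, with `position`, `mut_aa`, `mut_kd` columns
#'   added, ordered by position.
#' @export
scan_tm_candidates <- function(mutations, tm = tm_annotation(),
                               threshold = 0, sequence_window = NULL) {
  stopifnot(inherits(tm, "tm_annotation"))
  mut <- as.data.frame(mutations)
  if (!all(c("wt_aa", "position", "mut_aa") %in% names(mut))) {
    pc <- normalize_protein_change(mut$protein_change)
    if (anyNA(pc)) {
      warning("skipping ", sum(is.na(pc)), " unparsable protein change(s)")
    }
    mut$wt_aa <- substr(pc, 1L, 1L)
    mut$mut_aa <- substring(pc, nchar(pc))
    mut$position <- as.integer(gsub("[^0-9]", "", pc))
    mut <- mut[!is.na(pc), , drop = FALSE]
  }
  if (!is.null(sequence_window)) {
    out_of_window <- mut$position < sequence_window[1L] |
      mut$position > sequence_window[2L]
    if (any(out_of_window)) {
      warning("skipping ", sum(out_of_window),
              " mutation(s) outside the annotated sequence window")
      mut <- mut[!out_of_window, , drop = FALSE]
    }
  }
  missense <- mut$mut_aa != "*" & mut$mut_aa != mut$wt_aa
  central <- mut$position - tm$tm_start > tm$margin &
    tm$tm_end - mut$position > tm$margin
  hydrophilic <- rep(FALSE, nrow(mut))
  hydrophilic[missense] <- classify_hydrophilic(mut$mut_aa[missense],
                                                threshold)
  keep <- missense & central & hydrophilic
  out <- mut[keep, , drop = FALSE]
  out$mut_kd <- unname(KYTE_DOOLITTLE[out$mut_aa])
  out[order(out$position), , drop = FALSE]
}

#' Plot data for a hydropathy scan of catalogue mutations
#'
#' Tabulates, for external plotting, the wild-type profile of a sequence
#' window together with the mutant-residue hydropathies of catalogue
#' mutations, the layout of the transmembrane candidate figure.
#'
#' @param sequence Amino-acid string of the window.
#' @param numbering_offset Residue number of its first character.
#' @param mutations As in [scan_tm_candidates()].
#' @return A data.frame with `position`, `residue`, `kd`, `kind`
#'   (`wt` / `mutant`), `label`.
#' @export
hydropathy_plot_data <- function(sequence, numbering_offset, mutations) {
  prof <- kd_profile(sequence, numbering_offset)
  wt <- data.frame(position = prof$position, residue = prof$residue,
                   kd = prof$kd, kind = "wt",
                   label = paste0(prof$residue, prof$position),
                   stringsAsFactors = FALSE)
  pc <- normalize_protein_change(as.data.frame(mutations)$protein_change)
  pc <- pc[!is.na(pc)]
  pos <- as.integer(gsub("[^0-9]", "", pc))
  mut_aa <- substring(pc, nchar(pc))
  keep <- pos >= min(prof$position) & pos <= max(prof$position) &
    mut_aa %in% names(KYTE_DOOLITTLE)
  md <- data.frame(position = pos[keep], residue = mut_aa[keep],
                   kd = unname(KYTE_DOOLITTLE[mut_aa[keep]]), kind = "mutant",
                   label = pc[keep], stringsAsFactors = FALSE)
  rbind(wt, md)
}

#' Find small-x-x-x-small dimerization motifs
#'
#' Scans for the GxxxG-type transmembrane dimerization pattern: two
#' small-side-chain residues separated by any three residues. Overlapping
#' hits offset by one are additionally reported as the double pattern
#' small-small-x-x-small-small (the arrangement of the N-terminal TGMVGA
#' motif; the C-terminal ALGIG motif is a single hit).
#'
#' @param sequence Amino-acid string, length >= 5.
#' @param small_set Residues counting as small (default G, A, S, T).
#' @param numbering_offset Residue number of the first character.
#' @return A data.frame of class `motif_hits`: `start`, `pattern`
#'   (`small-x-x-x-small` or `small-small-x-x-small-small`),
#'   `subsequence`.
#' @export
find_small_x_motifs <- function(sequence, small_set = c("G", "A", "S", "T"),
                                numbering_offset = 1L) {
  res <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(res)
  if (n < 5L) stop("sequence shorter than one motif (5 residues)")
  small <- res %in% toupper(small_set)
  starts <- which(small[seq_len(n - 4L)] & small[seq(5L, n)])
  single <- data.frame(
    start = starts + as.integer(numbering_offset) - 1L,
    pattern = rep("small-x-x-x-small", length(starts)),
    subsequence = vapply(starts, function(i)
      paste(res[i:(i + 4L)], collapse = ""), character(1L)),
    stringsAsFactors = FALSE
  )
  dbl_starts <- starts[(starts + 1L) %in% starts]
  double <- data.frame(
    start = dbl_starts + as.integer(numbering_offset) - 1L,
    pattern = rep("small-small-x-x-small-small", length(dbl_starts)),
    subsequence = vapply(dbl_starts, function(i)
      paste(res[i:(i + 5L)], collapse = ""), character(1L)),
    stringsAsFactors = FALSE
  )
  out <- rbind(single, double)
  out <- out[order(out$start, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Read a TM-region mutation table from TSV
#'
#' Expects `protein_change` and optionally `occurrence_count` columns.
#'
#' @param path File path.
#' @return A data.frame usable by [scan_tm_candidates()].
#' @export
read_tm_mutations <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot("protein_change" %in% names(df))
  df
}
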