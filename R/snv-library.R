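#' Enumerate all single-nucleotide variants of a coding sequence
#'
#' Produces the exhaustive, duplicate-free library of single-nucleotide
#' substitutions: three alternative bases at each of the `3 * n_codons`
#' positions. A 3630-nt CDS therefore yields 10890 variants, the theoretical
#' diversity of an error-prone-PCR single-substitution library on a gene of
#' that length. Protein-change labels follow the `L858R` convention in the
#' numbering of the CDS; synonymous changes read e.g. `L927L`, stop gains end
#' in `*`.
#'
#' @param cds A [coding_sequence()].
#' @return A data.frame of class `snv_library` with one row per variant:
#'   `nt_pos`, `ref`, `alt`, `codon_index`, `aa_pos`, `ref_aa`, `alt_aa`,
#'   `protein_change`, `synonymous`, `true_activity` (initialized to 1.0,
#'   the wild-type level of relative ligand-independent activity).
#' @export
#' @examples
#' lib <- enumerate_snv_library(coding_sequence("ATGCTG"))
#' nrow(lib)  # 18
enumerate_snv_library <- function(cds) {
  stopifnot(inherits(cds, "coding_sequence"))
  bases <- c("A", "C", "G", "T")
  n <- cds_length(cds)
  ref <- strsplit(cds$nucleotides, "", fixed = TRUE)[[1L]]
  codons <- codon_split(cds$nucleotides)
  ref_aa_codon <- translate_codons(codons)

  nt_pos <- rep(seq_len(n), each = 3L)
  alt <- unlist(lapply(ref, function(b) bases[bases != b]), use.names = FALSE)
  ref_v <- ref[nt_pos]
  codon_index <- (nt_pos - 1L) %/% 3L + 1L
  within <- (nt_pos - 1L) %% 3L + 1L

  mut_codon <- codons[codon_index]
  substr(mut_codon, within, within) <- alt
  alt_aa <- translate_codons(mut_codon)
  ref_aa <- ref_aa_codon[codon_index]
  aa_pos <- codon_index + cds$numbering_offset - 1L

  out <- data.frame(
    nt_pos = nt_pos, ref = ref_v, alt = alt,
    codon_index = codon_index, aa_pos = aa_pos,
    ref_aa = ref_aa, alt_aa = alt_aa,
    protein_change = paste0(ref_aa, aa_pos, alt_aa),
    synonymous = ref_aa == alt_aa,
    true_activity = 1.0,
    stringsAsFactors = FALSE
  )
  class(out) <- c("snv_library", "data.frame")
  attr(out, "cds_id") <- cds$id
  attr(out, "n_nt") <- n
  out
}

#' Assign ground-truth activities to library variants
#'
#' Plants known relative activities (wild type = 1.0) onto the variants whose
#' protein change matches a key of `activating_map`; all other variants, and
#' all synonymous variants, keep activity 1.0. Keys that no single-nucleotide
#' change can produce are skipped with a warning and recorded in the
#' `skipped_keys` attribute, so parameter-recovery tests can verify that the
#' intended truth was actually planted.
#'
#' @param variants An `snv_library`.
#' @param activating_map Named numeric vector, names are protein changes
#'   (e.g. `c(L858R = 5)`), values are non-negative activities (0 = complete
#'   loss of function is allowed).
#' @return The library with `true_activity` updated; attribute
#'   `skipped_keys` lists unmatched map keys.
#' @export
assign_activities <- function(variants, activating_map = numeric()) {
  stopifnot(inherits(variants, "snv_library"))
  if (length(activating_map) == 0L) {
    attr(variants, "skipped_keys") <- character()
    return(variants)
  }
  stopifnot(!is.null(names(activating_map)), all(activating_map >= 0))
  keys <- names(activating_map)
  hit <- variants$protein_change %in% keys
  syn_hit <- hit & variants$synonymous
  if (any(syn_hit)) {
    warning("synonymous protein changes always keep activity 1.0: ",
            paste(unique(variants$protein_change[syn_hit]), collapse = ", "))
    hit <- hit & !variants$synonymous
  }
  variants$true_activity[hit] <-
    unname(activating_map[variants$protein_change[hit]])
  skipped <- setdiff(keys, variants$protein_change[!variants$synonymous])
  skipped <- setdiff(skipped, variants$protein_change[variants$synonymous])
  if (length(skipped) > 0L) {
    warning("activating_map keys not reachable by any single-nucleotide ",
            "change: ", paste(skipped, collapse = ", "))
  }
  attr(variants, "skipped_keys") <- skipped
  variants
}

#' Default planted activating set
#'
#' The five benchmark protein changes confirmed to trigger ligand-independent
#' receptor activation, each planted at 5x wild-type activity. Used as the
#' ground truth of the end-to-end recovery experiments.
#'
#' @param activity Activity assigned to each benchmark change.
#' @return Named numeric vector suitable for [assign_activities()].
#' @export
default_activating_map <- function(activity = 5.0) {
  setNames(rep(activity, 5L), c("S442I", "L658Q", "S768I", "T790M", "L858R"))
}
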