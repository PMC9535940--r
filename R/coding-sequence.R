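#' Coding sequences
#'
#' A `coding_sequence` is an in-frame nucleotide sequence with a residue
#' numbering offset, the substrate of SNV library enumeration. Numbering is
#' precursor numbering (signal peptide included), i.e. the convention in which
#' kinase-domain hotspots are called L858R or T790M.
#'
#' @param nucleotides Single string over `A`, `C`, `G`, `T`; length divisible
#'   by 3; no internal stop codon in frame (a terminal stop is allowed).
#' @param id Text label.
#' @param numbering_offset Residue number of the first codon (default 1).
#' @return An object of class `coding_sequence` with fields `id`,
#'   `nucleotides`, `numbering_offset`.
#' @export
#' @examples
#' cds <- coding_sequence("ATGGCTAAA")
#' cds_length(cds)
coding_sequence <- function(nucleotides, id = "cds", numbering_offset = 1L) {
  stopifnot(is.character(nucleotides), length(nucleotides) == 1L)
  nucleotides <- toupper(nucleotides)
  if (grepl("[^ACGT]", nucleotides)) {
    stop("coding sequence contains characters other than A, C, G, T")
  }
  n <- nchar(nucleotides)
  if (n == 0L || n %% 3L != 0L) {
    stop("coding sequence length must be a positive multiple of 3")
  }
  aa <- translate_codons(codon_split(nucleotides))
  internal <- aa[-length(aa)]
  if (any(internal == "*")) {
    stop("coding sequence contains an internal stop codon at codon ",
         which(internal == "*")[1L])
  }
  structure(
    list(id = as.character(id), nucleotides = nucleotides,
         numbering_offset = as.integer(numbering_offset)),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt (%d codons), first residue %d\n",
              x$id, nchar(x$nucleotides), nchar(x$nucleotides) %/% 3L,
              x$numbering_offset))
  invisible(x)
}

#' @rdname coding_sequence
#' @param cds A `coding_sequence`.
#' @export
cds_length <- function(cds) nchar(cds$nucleotides)

codon_split <- function(nt) {
  n <- nchar(nt)
  substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# Codon -> amino acid via the standard genetic code (one-letter, stop = "*").
translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

SENSE_CODONS <- local({
  bases <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  all3[Biostrings::GENETIC_CODE[all3] != "*"]
})

#' Random coding sequence without stop codons
#'
#' Draws codons uniformly from the 61 sense codons, optionally pinning chosen
#' residues to specific codons (useful to make particular protein changes
#' reachable by a single nucleotide substitution).
#'
#' @param n_codons Number of codons.
#' @param seed Optional integer seed.
#' @param id,numbering_offset Passed to [coding_sequence()].
#' @param fixed_codons Named character vector; names are residue numbers in
#'   the `numbering_offset` convention, values are codons.
#' @return A `coding_sequence`.
#' @export
random_coding_sequence <- function(n_codons, seed = NULL, id = "synthetic_cds",
                                   numbering_offset = 1L,
                                   fixed_codons = NULL) {
  stopifnot(n_codons >= 1)
  if (!is.null(seed)) set.seed(seed)
  codons <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  if (!is.null(fixed_codons)) {
    pos <- as.integer(names(fixed_codons)) - as.integer(numbering_offset) + 1L
    if (any(pos < 1L | pos > n_codons)) {
      stop("fixed_codons outside the coding sequence")
    }
    codons[pos] <- toupper(fixed_codons)
  }
  coding_sequence(paste(codons, collapse = ""), id = id,
                  numbering_offset = numbering_offset)
}

# Real codons at benchmark positions so that the canonical activating protein
# changes (and the classic artifact-prone C->T changes such as T790M) are
# reachable by one substitution on the synthetic receptor-like CDS.
EGFR_BENCHMARK_CODONS <- c(
  "289"  = "GCC",  # A289V via C->T
  "442"  = "AGC",  # S442I via G->T
  "652"  = "GGG",  # G652R via G->C/A at position 1
  "658"  = "CTG",  # L658Q via T->A
  "719"  = "GGC",  # G719S via G->A
  "768"  = "AGC",  # S768I via G->T
  "790"  = "ACG",  # T790M via C->T
  "858"  = "CTG",  # L858R via T->G
  "861"  = "CTG",  # L861Q via T->A
  "927"  = "CTG",  # synonymous L927L reachable (e.g. CTG->CTA)
  "1129" = "CAC"   # H1129Y via C->T
)

#' Synthetic receptor-like coding sequence
#'
#' A 1210-codon (3630 nt) random sense-codon CDS in which the benchmark
#' residues of the screen (S442, L658, S768, T790, L858, ...) carry their real
#' codons, so the corresponding protein changes exist in the enumerated SNV
#' library. Everything else is random; this is a synthetic stand-in, not the
#' real receptor CDS.
#'
#' @param seed Integer seed for the random filler codons.
#' @param n_codons Number of codons (default 1210, i.e. 3630 nt).
#' @return A `coding_sequence` numbered from residue 1.
#' @export
synthetic_egfr_cds <- function(seed = 1L, n_codons = 1210L) {
  fixed <- EGFR_BENCHMARK_CODONS[as.integer(names(EGFR_BENCHMARK_CODONS)) <= n_codons]
  random_coding_sequence(n_codons, seed = seed, id = "synthetic_egfr_like",
                         numbering_offset = 1L, fixed_codons = fixed)
}

# Transmembrane neighborhood P631-L683 of the receptor precursor (UniProt
# P00533 numbering, with M650/M668 as in the database sequence). Residue 631
# is the first character.
EGFR_TM_REGION_START <- 631L
EGFR_TM_REGION <- "PGLEGCPTNGPKIPSIATGMVGALLLLLVVALGIGLFMRRRHIVRKRTLRRLL"

#' Transmembrane segment sequences of the receptor
#'
#' Returns stretches of the transmembrane neighborhood in precursor numbering:
#' `"scan"` is the P631-L683 window used for the hydropathy scan, `"tm"` the
#' annotated transmembrane helix I646-M668, and `"dimer"` the 30-residue
#' K642-R671 segment used for helix-dimer fixtures (M650/M668 as in the
#' database sequence).
#'
#' @param region One of `"scan"`, `"tm"`, `"dimer"`.
#' @return A character string; attribute `offset` gives the residue number of
#'   its first character.
#' @export
egfr_tm_sequence <- function(region = c("scan", "tm", "dimer")) {
  region <- match.arg(region)
  rng <- switch(region,
    scan  = c(631L, 683L),
    tm    = c(646L, 668L),
    dimer = c(642L, 671L)
  )
  s <- substr(EGFR_TM_REGION, rng[1] - EGFR_TM_REGION_START + 1L,
              rng[2] - EGFR_TM_REGION_START + 1L)
  structure(s, offset = rng[1])
}

#' Read / write coding sequences as FASTA
#'
#' Thin wrappers around Biostrings FASTA I/O keeping the numbering offset in
#' the record description (`offset=<n>`).
#'
#' @param path File path.
#' @param numbering_offset Used if the FASTA description carries no
#'   `offset=` tag.
#' @return `read_coding_sequence` returns a `coding_sequence`;
#'   `write_coding_sequence` returns `path` invisibly.
#' @export
read_coding_sequence <- function(path, numbering_offset = 1L) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 1L) stop("no FASTA record in ", path)
  nm <- names(set)[1L]
  off <- numbering_offset
  m <- regmatches(nm, regexpr("offset=-?[0-9]+", nm))
  if (length(m) == 1L) off <- as.integer(sub("offset=", "", m))
  coding_sequence(as.character(set[[1L]]),
                  id = sub("\\s.*$", "", nm), numbering_offset = off)
}

#' @rdname read_coding_sequence
#' @param cds A `coding_sequence`.
#' @export
write_coding_sequence <- function(cds, path) {
  set <- Biostrings::DNAStringSet(cds$nucleotides)
  names(set) <- sprintf("%s offset=%d", cds$id, cds$numbering_offset)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
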