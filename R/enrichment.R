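#' Per-variant frequencies from read counts
#'
#' Frequency is the exact rational ratio count / per-position coverage of the
#' same condition, with no smoothing. Matches per-nucleotide variant calling:
#' the denominator is the coverage at the variant's position in that
#' condition, not the total read count of the library.
#'
#' @param table A [variant_count_table()].
#' @return A data.frame of class `frequency_table`: variant key columns plus
#'   one frequency column per condition; the `coverage` attribute is carried
#'   along.
#' @export
compute_frequencies <- function(table) {
  stopifnot(inherits(table, "variant_count_table"))
  conds <- conditions(table)
  cov <- coverage_of(table)
  pos <- as.character(table$nt_pos)
  out <- as.data.frame(table)[setdiff(names(table), conds)]
  for (cond in conds) {
    cv <- cov[pos, cond]
    cnt <- table[[cond]]
    if (any(cv <= 0 & cnt > 0)) {
      stop("count > 0 with zero coverage in condition ", cond)
    }
    if (any(cv <= 0)) stop("coverage must be positive at counted positions")
    out[[cond]] <- cnt / cv
  }
  attr(out, "coverage") <- cov
  attr(out, "conditions") <- conds
  class(out) <- c("frequency_table", "data.frame")
  out
}

variant_key <- function(x) paste(x$nt_pos, x$ref, x$alt, sep = ":")

check_conditions <- function(freqs, conds) {
  missing <- setdiff(conds, conditions(freqs))
  if (length(missing) > 0L) {
    stop("unknown condition(s): ", paste(missing, collapse = ", "))
  }
}

#' Filter 1: frequency after activation selection
#'
#' Keeps variants whose frequency strictly exceeds `threshold` in at least
#' one of the named activation-selected conditions (OR across experiments;
#' per-experiment flags are retained by the pipeline report).
#'
#' @param freqs A [compute_frequencies()] result.
#' @param conditions Names of the activation-selected conditions.
#' @param threshold Strict frequency threshold (default 0.01, i.e. > 1%).
#' @return Character vector of variant keys (`nt_pos:ref:alt`).
#' @export
filter_frequency <- function(freqs, conditions, threshold = 0.01) {
  stopifnot(inherits(freqs, "frequency_table"))
  check_conditions(freqs, conditions)
  f <- as.matrix(as.data.frame(freqs)[conditions])
  variant_key(freqs)[rowSums(f > threshold) > 0L]
}

#' Filter 2: fold enrichment over the loss-of-function reference
#'
#' Keeps variants whose activation-selected frequency strictly exceeds
#' `fold` times the reference frequency in at least one activation condition.
#' When several reference conditions are given, the maximum (most
#' conservative) reference frequency is used. A reference frequency of zero
#' is replaced by the pseudofrequency `0.5 / coverage` at that position,
#' avoiding infinite ratios while preserving ordering.
#'
#' @param freqs A [compute_frequencies()] result.
#' @param activation_conditions Names of activation-selected conditions.
#' @param reference_conditions Names of loss-of-function reference
#'   conditions.
#' @param fold Strict fold threshold (default 8, i.e. > 8-fold).
#' @return Character vector of variant keys.
#' @export
filter_fold_enrichment <- function(freqs, activation_conditions,
                                   reference_conditions, fold = 8) {
  stopifnot(inherits(freqs, "frequency_table"))
  check_conditions(freqs, c(activation_conditions, reference_conditions))
  cov <- attr(freqs, "coverage")
  pos <- as.character(freqs$nt_pos)
  fr <- as.matrix(as.data.frame(freqs)[reference_conditions])
  ref_cov <- cov[pos, reference_conditions, drop = FALSE]
  fr[fr == 0] <- 0.5 / ref_cov[fr == 0]
  f_ref <- apply(fr, 1L, max)
  fa <- as.matrix(as.data.frame(freqs)[activation_conditions])
  variant_key(freqs)[rowSums(fa / f_ref > fold) > 0L]
}

#' Catalogue fixtures of somatic mutations
#'
#' A minimal stand-in for a somatic-mutation catalogue: protein-level
#' substitutions (including synonymous notation such as `L927L`) with
#' occurrence counts of at least 1.
#'
#' @param protein_change Character vector of substitution labels.
#' @param occurrence_count Integer vector (>= 1).
#' @return A data.frame of class `cosmic_fixture`.
#' @export
cosmic_fixture <- function(protein_change, occurrence_count = 1L) {
  occurrence_count <- rep_len(as.integer(occurrence_count),
                              length(protein_change))
  if (any(occurrence_count < 1L)) stop("occurrence_count must be >= 1")
  out <- data.frame(protein_change = as.character(protein_change),
                    occurrence_count = occurrence_count,
                    stringsAsFactors = FALSE)
  class(out) <- c("cosmic_fixture", "data.frame")
  out
}

#' Read a catalogue fixture from TSV
#'
#' Expects columns `protein_change` and `occurrence_count`.
#'
#' @param path File path.
#' @return A [cosmic_fixture()].
#' @export
read_cosmic_fixture <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  cosmic_fixture(df$protein_change, df$occurrence_count)
}

# Normalize a protein-change label to <AA><number><AA|*>; NA if impossible.
normalize_protein_change <- function(x) {
  x <- toupper(trimws(x))
  x <- sub("^P\\.", "", x)
  ok <- grepl("^[A-Z][0-9]+[A-Z*]$", x)
  x[!ok] <- NA_character_
  x
}

#' Filter 3: catalogue membership
#'
#' Keeps variants whose (normalized) protein change appears in the catalogue
#' fixture. Membership is tested on protein labels, including synonymous
#' notation; unnormalizable labels are excluded with a warning.
#'
#' @param variants Data.frame carrying `protein_change` (e.g. a
#'   `frequency_table`).
#' @param cosmic A [cosmic_fixture()].
#' @return Character vector of variant keys (or protein changes if no
#'   nucleotide keys are present).
#' @export
filter_cosmic <- function(variants, cosmic) {
  stopifnot(inherits(cosmic, "cosmic_fixture"))
  pc <- normalize_protein_change(variants$protein_change)
  if (anyNA(pc)) {
    warning("excluding ", sum(is.na(pc)),
            " variant(s) with unnormalizable protein-change labels")
  }
  keep <- !is.na(pc) & pc %in% normalize_protein_change(cosmic$protein_change)
  if (all(c("nt_pos", "ref", "alt") %in% names(variants))) {
    variant_key(variants)[keep]
  } else {
    variants$protein_change[keep]
  }
}

#' Run the three-filter enrichment pipeline
#'
#' Applies, in any order (the result is their intersection), (1) frequency
#' > `freq_threshold` in at least one activation-selected condition, (2)
#' > `fold`-fold higher frequency than in the loss-of-function reference,
#' and (3) catalogue membership. Reports per-variant, per-filter flags and
#' per-experiment provenance.
#'
#' @param table A [variant_count_table()].
#' @param cosmic A [cosmic_fixture()].
#' @param activation_conditions Activation-selected condition names.
#' @param reference_conditions Loss-of-function condition names.
#' @param freq_threshold Filter-1 threshold (strict >).
#' @param fold Filter-2 fold threshold (strict >).
#' @return A data.frame of class `filter_report`: variant keys, per-condition
#'   frequencies, reference frequency, fold enrichment, `pass_filter1/2/3`,
#'   `verdict` (the AND of the three), and one `hit_<condition>` flag per
#'   activation condition. The surviving protein changes are in
#'   `attr(, "survivors")`.
#' @export
run_filter_pipeline <- function(table, cosmic, activation_conditions,
                                reference_conditions, freq_threshold = 0.01,
                                fold = 8) {
  freqs <- compute_frequencies(table)
  key <- variant_key(freqs)
  f1 <- key %in% filter_frequency(freqs, activation_conditions,
                                  freq_threshold)
  f2 <- key %in% filter_fold_enrichment(freqs, activation_conditions,
                                        reference_conditions, fold)
  f3 <- key %in% filter_cosmic(freqs, cosmic)

  cov <- attr(freqs, "coverage")
  pos <- as.character(freqs$nt_pos)
  fr <- as.matrix(as.data.frame(freqs)[reference_conditions])
  ref_cov <- cov[pos, reference_conditions, drop = FALSE]
  fr[fr == 0] <- 0.5 / ref_cov[fr == 0]
  f_ref <- apply(fr, 1L, max)
  fa <- as.matrix(as.data.frame(freqs)[activation_conditions])

  report <- data.frame(
    nt_pos = freqs$nt_pos, ref = freqs$ref, alt = freqs$alt,
    protein_change = freqs$protein_change,
    as.data.frame(fa), reference_frequency = f_ref,
    fold_enrichment = apply(fa, 1L, max) / f_ref,
    pass_filter1 = f1, pass_filter2 = f2, pass_filter3 = f3,
    verdict = f1 & f2 & f3,
    stringsAsFactors = FALSE
  )
  for (cond in activation_conditions) {
    report[[paste0("hit_", cond)]] <-
      fa[, cond] > freq_threshold & fa[, cond] / f_ref > fold & f3
  }
  attr(report, "survivors") <- unique(report$protein_change[report$verdict])
  class(report) <- c("filter_report", "data.frame")
  report
}

#' @export
print.filter_report <- function(x, ...) {
  surv <- attr(x, "survivors")
  cat(sprintf("<filter_report> %d variants, %d pass all three filters\n",
              nrow(x), sum(x$verdict)))
  if (length(surv) > 0L) {
    cat("survivors:", paste(surv, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Coverage quality control
#'
#' Flags conditions whose mean per-position coverage falls below `mean_min`
#' or with any position below `per_position_min` (the screen's published
#' thresholds are a mean above 100,000 and above 40,000 everywhere).
#'
#' @param table A [variant_count_table()].
#' @param mean_min Minimum mean coverage per condition.
#' @param per_position_min Minimum per-position coverage.
#' @return A data.frame with one row per condition: `condition`,
#'   `mean_coverage`, `min_coverage`, `n_below_min`, `pass`; attribute
#'   `failing_positions` lists offending positions per condition. An empty
#'   table yields zero rows and attribute `valid = FALSE`.
#' @export
coverage_qc <- function(table, mean_min = 1e5, per_position_min = 4e4) {
  stopifnot(inherits(table, "variant_count_table"))
  cov <- coverage_of(table)
  if (nrow(cov) == 0L) {
    out <- data.frame(condition = character(), mean_coverage = numeric(),
                      min_coverage = numeric(), n_below_min = integer(),
                      pass = logical())
    attr(out, "valid") <- FALSE
    return(out)
  }
  conds <- colnames(cov)
  fails <- lapply(conds, function(cond)
    as.integer(rownames(cov)[cov[, cond] < per_position_min]))
  names(fails) <- conds
  out <- data.frame(
    condition = conds,
    mean_coverage = colMeans(cov),
    min_coverage = apply(cov, 2L, min),
    n_below_min = vapply(fails, length, integer(1L)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$pass <- out$mean_coverage >= mean_min & out$n_below_min == 0L
  attr(out, "failing_positions") <- fails
  attr(out, "valid") <- TRUE
  out
}

#' Path to a packaged example file
#'
#' @param file File name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return A file path, or a vector of file names.
#' @export
pfseq_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "pfseq"))
  } else {
    path <- system.file("extdata", file, package = "pfseq", mustWork = TRUE)
    path
  }
}

#' Write a filter report as TSV plus a human-readable summary
#'
#' @param report A [run_filter_pipeline()] result.
#' @param path TSV output path; the summary goes to `<path>.txt`.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  surv <- attr(report, "survivors")
  summary_lines <- c(
    sprintf("%d variants scored; %d pass all three filters",
            nrow(report), sum(report$verdict)),
    sprintf("survivors: %s",
            if (length(surv)) paste(surv, collapse = ", ") else "(none)"))
  writeLines(summary_lines, paste0(path, ".txt"))
  invisible(path)
}
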