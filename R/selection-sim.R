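#' Selection / sequencing configuration
#'
#' Parameters of the simulated screen. `gate_stringency` is the fraction of
#' cells passing the sort gate; the per-round enrichment factor of a variant
#' with activity `a` is `a^s` with `s = -log(gate_stringency)`, so stringency
#' 1 is neutral and tighter gates discriminate more sharply.
#' `depth_per_round` is the per-nucleotide sequencing coverage of each
#' condition. `pcr_error_rate` is the per-base, per-substitution-type rate of
#' amplification artifacts; C->T artifacts occur at `pcr_error_rate *
#' ct_bias_factor`, emulating the C->T-biased noise of post-sort
#' amplification. `library_mutant_fraction` is the fraction of molecules in
#' the unselected library carrying (one) mutation.
#'
#' @param rounds Number of selection rounds (>= 0).
#' @param gate_stringency Real in (0, 1].
#' @param depth_per_round Positive integer, reads per nucleotide position.
#' @param pcr_error_rate Per-base per-substitution artifact rate in \[0, 1\].
#' @param ct_bias_factor Multiplier (>= 1) on the C->T artifact rate.
#' @param mirror_ga If `TRUE`, apply the same bias to G->A on the plotted
#'   strand (off by default; the bias direction is stated for C->T only).
#' @param library_mutant_fraction Real in (0, 1).
#' @param seed Integer seed.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(rounds = 2L, gate_stringency = 0.05,
                             depth_per_round = 1e6,
                             pcr_error_rate = 0, ct_bias_factor = 10,
                             mirror_ga = FALSE,
                             library_mutant_fraction = 0.7,
                             seed = 1L) {
  stopifnot(rounds >= 0, depth_per_round > 0,
            gate_stringency > 0, gate_stringency <= 1,
            pcr_error_rate >= 0, pcr_error_rate <= 1, ct_bias_factor >= 1,
            library_mutant_fraction > 0, library_mutant_fraction < 1)
  if (pcr_error_rate * ct_bias_factor > 1) {
    stop("pcr_error_rate * ct_bias_factor exceeds 1")
  }
  structure(list(rounds = as.integer(rounds),
                 gate_stringency = gate_stringency,
                 depth_per_round = as.integer(depth_per_round),
                 pcr_error_rate = pcr_error_rate,
                 ct_bias_factor = ct_bias_factor,
                 mirror_ga = isTRUE(mirror_ga),
                 library_mutant_fraction = library_mutant_fraction,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Per-variant read-count tables
#'
#' The substrate of the filter pipeline: one row per nucleotide variant with
#' one integer count column per condition, plus per-position, per-condition
#' coverage held in the `coverage` attribute (matrix positions x conditions).
#' At every position and condition the three alternative-base counts sum to
#' at most the coverage.
#'
#' @param variants Data.frame with at least `nt_pos`, `ref`, `alt`,
#'   `protein_change`.
#' @param counts Integer matrix, rows matching `variants`, named condition
#'   columns.
#' @param coverage Integer matrix, rows = positions present in
#'   `variants$nt_pos` (rownames = position), same condition columns.
#' @return A data.frame of class `variant_count_table`.
#' @export
variant_count_table <- function(variants, counts, coverage) {
  stopifnot(nrow(variants) == nrow(counts),
            identical(colnames(counts), colnames(coverage)),
            !is.null(colnames(counts)))
  cov_row <- match(as.character(variants$nt_pos), rownames(coverage))
  if (anyNA(cov_row)) stop("coverage missing for some variant positions")
  if (any(counts > coverage[cov_row, , drop = FALSE])) {
    stop("variant count exceeds coverage at its position")
  }
  keep <- intersect(c("nt_pos", "ref", "alt", "protein_change", "aa_pos",
                      "ref_aa", "alt_aa", "synonymous", "true_activity"),
                    names(variants))
  out <- cbind(as.data.frame(variants)[keep], as.data.frame(counts))
  attr(out, "coverage") <- coverage
  attr(out, "conditions") <- colnames(counts)
  class(out) <- c("variant_count_table", "data.frame")
  out
}

#' @export
print.variant_count_table <- function(x, ...) {
  cat(sprintf("<variant_count_table> %d variants, conditions: %s\n",
              nrow(x), paste(attr(x, "conditions"), collapse = ", ")))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}

conditions <- function(table) attr(table, "conditions")
coverage_of <- function(table) attr(table, "coverage")

# Multinomial read sampling: at every position draw (alt1, alt2, alt3, wt)
# reads at the given depth from the variant molecule frequencies.
# idx_by_pos is a list of row indices per position (from split()).
sample_position_counts <- function(q, idx_by_pos, depth) {
  counts <- integer(length(q))
  for (idx in idx_by_pos) {
    probs <- c(q[idx], max(0, 1 - sum(q[idx])))
    counts[idx] <- rmultinom(1L, depth, probs)[seq_along(idx), 1L]
  }
  counts
}

# Row indices per nucleotide position, in increasing position order.
position_index <- function(nt_pos) {
  idx <- split(seq_along(nt_pos), nt_pos)
  idx[order(as.integer(names(idx)))]
}

#' Simulate read counts across selection rounds
#'
#' Generative emulation of the sort-and-sequence cycle: molecule frequencies
#' start uniform over the library (total mutant fraction
#' `library_mutant_fraction`, remainder wild type), each round multiplies a
#' variant's expected abundance by the enrichment factor `activity^s`
#' (`s = -log(gate_stringency)`; for the loss-of-function reference selection
#' the exponent is `-s`, favoring inactive variants), frequencies are
#' renormalized, and read counts are drawn by per-position multinomial
#' sampling at `depth_per_round`. The output holds the unselected input
#' condition plus one condition per round.
#'
#' @param variants An `snv_library` with activities assigned.
#' @param config A [selection_config()]; its `seed` is used unless
#'   overridden.
#' @param mode `"activation"` (sort for phospho-positive cells) or
#'   `"loss_of_function"` (reference selection for inactive variants).
#' @param condition_prefix Prefix of round condition names (default `"act"`
#'   or `"lof"`), yielding e.g. `act_r1`, `act_r2`.
#' @param include_input Include the unselected `input` condition.
#' @param seed Optional override of `config$seed`.
#' @return A [variant_count_table()].
#' @export
simulate_selection_counts <- function(variants, config,
                                      mode = c("activation",
                                               "loss_of_function"),
                                      condition_prefix = NULL,
                                      include_input = TRUE,
                                      seed = config$seed) {
  stopifnot(inherits(variants, "snv_library"),
            inherits(config, "selection_config"))
  mode <- match.arg(mode)
  if (is.null(condition_prefix)) {
    condition_prefix <- if (mode == "activation") "act" else "lof"
  }
  if (!is.null(seed)) set.seed(seed)

  nv <- nrow(variants)
  q <- rep(config$library_mutant_fraction / nv, nv)
  if (sum(q) <= 0) stop("zero total abundance")
  s <- -log(config$gate_stringency)
  act <- pmax(variants$true_activity, 1e-6)
  w <- if (mode == "activation") act^s else act^(-s)

  idx_by_pos <- position_index(variants$nt_pos)
  positions <- as.integer(names(idx_by_pos))
  cond_names <- c(if (include_input) "input",
                  if (config$rounds > 0)
                    paste0(condition_prefix, "_r", seq_len(config$rounds)))
  counts <- matrix(0L, nv, length(cond_names),
                   dimnames = list(NULL, cond_names))
  if (include_input) {
    counts[, "input"] <- sample_position_counts(q, idx_by_pos,
                                                config$depth_per_round)
  }
  for (r in seq_len(config$rounds)) {
    qw <- q * w
    q <- qw / (sum(qw) + (1 - sum(q)))  # wild-type pool has weight 1
    counts[, paste0(condition_prefix, "_r", r)] <-
      sample_position_counts(q, idx_by_pos, config$depth_per_round)
  }
  cov <- matrix(config$depth_per_round, length(positions), length(cond_names),
                dimnames = list(as.character(positions), cond_names))
  variant_count_table(variants, counts, cov)
}

#' Overlay PCR amplification artifacts on a count table
#'
#' Reassigns reads from the wild-type pool of every position to artifact
#' substitutions: at each position and condition the wild-type reads are
#' redistributed multinomially with per-substitution probability
#' `pcr_error_rate`, multiplied by `ct_bias_factor` for C->T (and, if
#' `mirror_ga`, for G->A) on the coding strand. Column sums (coverage) are
#' conserved exactly; artifact reads displace true reads, they are never
#' invented.
#'
#' @param table A [variant_count_table()].
#' @param config A [selection_config()] supplying the rates.
#' @param seed Optional seed (defaults to `config$seed + 1000`).
#' @return The table with artifact counts added.
#' @export
apply_pcr_noise <- function(table, config, seed = config$seed + 1000L) {
  stopifnot(inherits(table, "variant_count_table"),
            inherits(config, "selection_config"))
  if (config$pcr_error_rate == 0) return(table)
  if (!is.null(seed)) set.seed(seed)
  cov <- coverage_of(table)
  conds <- conditions(table)
  idx_by_pos <- position_index(table$nt_pos)

  for (cond in conds) {
    col <- table[[cond]]
    for (p in names(idx_by_pos)) {
      idx <- idx_by_pos[[p]]
      ref_base <- table$ref[idx[1L]]
      rates <- rep(config$pcr_error_rate, length(idx))
      biased <- (ref_base == "C" & table$alt[idx] == "T") |
        (config$mirror_ga & ref_base == "G" & table$alt[idx] == "A")
      rates[biased] <- rates[biased] * config$ct_bias_factor
      if (sum(rates) > 1) stop("artifact rates at position ", p, " sum to > 1")
      wt <- cov[p, cond] - sum(col[idx])
      if (wt <= 0) next
      art <- rmultinom(1L, wt, c(rates, 1 - sum(rates)))[seq_along(idx), 1L]
      col[idx] <- col[idx] + art
    }
    table[[cond]] <- col
  }
  table
}

#' Merge count tables sharing the same variant rows
#'
#' Used to assemble a full screen (input, activation experiments A/B,
#' loss-of-function reference) into one table. Tables must describe the same
#' variants in the same order; condition names must not collide.
#'
#' @param ... `variant_count_table` objects.
#' @return A single [variant_count_table()].
#' @export
combine_count_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L)
  key <- function(t) paste(t$nt_pos, t$ref, t$alt)
  k0 <- key(tabs[[1L]])
  for (t in tabs[-1L]) {
    if (!identical(key(t), k0)) stop("tables do not share identical variants")
  }
  all_conds <- unlist(lapply(tabs, conditions))
  if (anyDuplicated(all_conds)) stop("duplicate condition names: ",
                                     paste(unique(all_conds[duplicated(all_conds)]),
                                           collapse = ", "))
  counts <- do.call(cbind, lapply(tabs, function(t)
    as.matrix(as.data.frame(t)[conditions(t)])))
  cov <- do.call(cbind, lapply(tabs, coverage_of))
  variant_count_table(as.data.frame(tabs[[1L]]), counts, cov)
}

#' Simulate a full two-experiment screen
#'
#' Convenience wrapper reproducing the screen layout: one shared unselected
#' input library, independent activation selections (experiments named in
#' `experiments`, each with `config$rounds` rounds), and one loss-of-function
#' reference selection. PCR artifacts, if configured
#' (`config$pcr_error_rate > 0`), are overlaid on every sequenced condition,
#' emulating noise introduced during post-sort amplification.
#'
#' @param variants An `snv_library` with activities assigned.
#' @param config A [selection_config()].
#' @param experiments Character vector of activation experiment labels.
#' @return A [variant_count_table()] with conditions `input`,
#'   `act<EXP>_r<k>`, `lof_r<k>`.
#' @export
simulate_screen <- function(variants, config, experiments = c("A", "B")) {
  tabs <- list(
    simulate_selection_counts(variants, config, "activation",
                              condition_prefix = "unused",
                              include_input = TRUE, seed = config$seed)
  )
  # keep only the shared input from the first draw
  input_tab <- tabs[[1L]]
  input_counts <- as.matrix(as.data.frame(input_tab)["input"])
  input_cov <- coverage_of(input_tab)[, "input", drop = FALSE]
  tabs <- list(variant_count_table(as.data.frame(input_tab), input_counts,
                                   input_cov))
  for (i in seq_along(experiments)) {
    tabs[[length(tabs) + 1L]] <- simulate_selection_counts(
      variants, config, "activation",
      condition_prefix = paste0("act", experiments[i]),
      include_input = FALSE, seed = config$seed + 17L * i)
  }
  tabs[[length(tabs) + 1L]] <- simulate_selection_counts(
    variants, config, "loss_of_function", condition_prefix = "lof",
    include_input = FALSE, seed = config$seed + 811L)
  out <- do.call(combine_count_tables, tabs)
  if (config$pcr_error_rate > 0) {
    out <- apply_pcr_noise(out, config, seed = config$seed + 1000L)
  }
  out
}

#' Read / write variant count tables as TSV
#'
#' Columns: `nt_pos`, `ref`, `alt`, `protein_change`, one count column per
#' condition, and one `cov_<condition>` column giving the per-position
#' coverage of that condition.
#'
#' @param table A [variant_count_table()].
#' @param path File path.
#' @return `read_count_table` returns a [variant_count_table()];
#'   `write_count_table` returns `path` invisibly.
#' @export
write_count_table <- function(table, path) {
  conds <- conditions(table)
  cov <- coverage_of(table)
  df <- as.data.frame(table)
  for (cond in conds) {
    df[[paste0("cov_", cond)]] <- cov[as.character(df$nt_pos), cond]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "#")
  cov_cols <- grep("^cov_", names(df), value = TRUE)
  conds <- sub("^cov_", "", cov_cols)
  if (length(conds) == 0L) stop("no cov_<condition> columns in ", path)
  positions <- as.character(sort(unique(df$nt_pos)))
  cov <- matrix(NA_integer_, length(positions), length(conds),
                dimnames = list(positions, conds))
  for (cond in conds) {
    cov[as.character(df$nt_pos), cond] <- df[[paste0("cov_", cond)]]
  }
  counts <- as.matrix(df[conds])
  meta <- df[setdiff(names(df), c(conds, cov_cols))]
  variant_count_table(meta, counts, cov)
}
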