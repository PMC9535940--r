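test_that("compute_frequencies is exact division, cross-checked row by
           row", {
  tab <- toy_count_table()
  freqs <- compute_frequencies(tab)
  expect_equal(freqs$act, c(0.015, 0, 0.12))
  expect_equal(freqs$lof, c(5, 3, 900) / 10000)

  # brute-force recomputation on a simulated table agrees exactly
  lib <- enumerate_snv_library(random_coding_sequence(15, seed = 30))
  cfg <- selection_config(rounds = 1, depth_per_round = 5e4, seed = 31)
  sim <- simulate_selection_counts(lib, cfg)
  fr <- compute_frequencies(sim)
  cov <- attr(sim, "coverage")
  for (cond in c("input", "act_r1")) {
    manual <- vapply(seq_len(nrow(sim)), function(i)
      sim[[cond]][i] / cov[as.character(sim$nt_pos[i]), cond], numeric(1))
    expect_identical(fr[[cond]], manual)
  }
})

test_that("filter_frequency applies a strict threshold, matching a
           brute-force scan", {
  tab <- toy_count_table()
  freqs <- compute_frequencies(tab)
  expect_equal(filter_frequency(freqs, "act"), c("10:C:T", "20:G:A"))
  # boundary: exactly 1% is excluded
  tab2 <- toy_count_table()
  tab2$act <- c(100L, 120L, 99L)  # 0.010, 0.012, 0.0099
  f2 <- compute_frequencies(tab2)
  expect_equal(filter_frequency(f2, "act"), "11:A:G")
  expect_error(filter_frequency(freqs, "nope"), "unknown condition")

  # exhaustive check on a larger mixed table
  set.seed(32)
  n <- 20
  v <- data.frame(nt_pos = seq_len(n), ref = "A", alt = "G",
                  protein_change = paste0("X", seq_len(n), "Y"))
  counts <- cbind(act = as.integer(runif(n, 0, 300)))
  cov <- matrix(10000L, n, 1, dimnames = list(seq_len(n), "act"))
  fr <- compute_frequencies(variant_count_table(v, counts, cov))
  expect_setequal(filter_frequency(fr, "act"),
                  paste(v$nt_pos, "A", "G", sep = ":")[counts[, 1] / 10000 > 0.01])
})

test_that("filter_fold_enrichment uses a strict fold and the pseudocount
           policy for zero reference frequency", {
  v <- data.frame(nt_pos = 1:3, ref = "A", alt = "G",
                  protein_change = c("A1V", "A2V", "A3V"))
  counts <- cbind(act = c(1600L, 800L, 10L), lof = c(100L, 100L, 0L))
  cov <- matrix(c(rep(100000L, 3), rep(100000L, 3)), 3,
                dimnames = list(1:3, c("act", "lof")))
  fr <- compute_frequencies(variant_count_table(v, counts, cov))
  kept <- filter_fold_enrichment(fr, "act", "lof", fold = 8)
  # ratios: 16 (kept), 8 exactly (excluded), and 1e-4 / (0.5/1e5) = 20 (kept)
  expect_setequal(kept, c("1:A:G", "3:A:G"))
})

test_that("filter_cosmic is protein-level membership including synonymous
           labels", {
  cos <- read_cosmic_fixture(pfseq_example("cosmic_egfr_synthetic.tsv"))
  v <- data.frame(nt_pos = 1:3, ref = "A", alt = "G",
                  protein_change = c("L858R", "Q1021K", "L927L"))
  expect_equal(filter_cosmic(v, cos), c("1:A:G", "3:A:G"))
  v$protein_change[2] <- "not-a-label"
  expect_warning(keep <- filter_cosmic(v, cos), "unnormalizable")
  expect_equal(keep, c("1:A:G", "3:A:G"))
})

test_that("run_filter_pipeline reproduces the worked example and is an
           order-independent intersection", {
  tab <- read_count_table(pfseq_example("screen_counts_synthetic.tsv"))
  cos <- read_cosmic_fixture(pfseq_example("cosmic_egfr_synthetic.tsv"))
  rep <- run_filter_pipeline(tab, cos, c("actA", "actB"), "lof")
  expect_setequal(attr(rep, "survivors"),
                  c("S442I", "L658Q", "S768I", "T790M", "L858R",
                    "L927L", "H1129Y"))
  expect_equal(sum(rep$verdict), 7L)
  # each decoy fails exactly one filter
  decoys <- rep[rep$protein_change %in% c("A289V", "L861Q", "M600T"), ]
  expect_equal(rowSums(!decoys[c("pass_filter1", "pass_filter2",
                                 "pass_filter3")]),
               setNames(rep(1, 3), rownames(decoys)))
  # verdict is the AND of the flags, hence order-independent
  expect_identical(rep$verdict,
                   rep$pass_filter1 & rep$pass_filter2 & rep$pass_filter3)
  freqs <- compute_frequencies(tab)
  manual <- Reduce(intersect, list(
    filter_frequency(freqs, c("actA", "actB")),
    filter_fold_enrichment(freqs, c("actA", "actB"), "lof"),
    filter_cosmic(freqs, cos)))
  expect_setequal(paste(rep$nt_pos, rep$ref, rep$alt, sep = ":")[rep$verdict],
                  manual)

  empty <- run_filter_pipeline(tab, cosmic_fixture("Z999Z"),
                               c("actA", "actB"), "lof")
  expect_length(attr(empty, "survivors"), 0)
})

test_that("raising any threshold never enlarges the surviving set, and
           filters are idempotent", {
  tab <- read_count_table(pfseq_example("screen_counts_synthetic.tsv"))
  freqs <- compute_frequencies(tab)
  prev <- NULL
  for (thr in c(0.001, 0.01, 0.02, 0.05)) {
    kept <- filter_frequency(freqs, c("actA", "actB"), thr)
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
  prev <- NULL
  for (fold in c(2, 8, 32)) {
    kept <- filter_fold_enrichment(freqs, c("actA", "actB"), "lof", fold)
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
  # idempotence: re-applying a filter to its own output is a no-op
  kept <- filter_frequency(freqs, "actA")
  sub <- freqs[paste(freqs$nt_pos, freqs$ref, freqs$alt, sep = ":") %in% kept, ]
  attr(sub, "coverage") <- attr(freqs, "coverage")
  attr(sub, "conditions") <- attr(freqs, "conditions")
  class(sub) <- class(freqs)
  expect_setequal(filter_frequency(sub, "actA"), kept)
})

test_that("scaled-down simulated selections recover planted truth through
           filters 1+2", {
  # acceptance runs the full 10-seed depth-1e6 experiment; this is a fast
  # 2-seed depth-1e5 version of the same stated world
  lib <- assign_activities(enumerate_snv_library(synthetic_egfr_cds(40)),
                           default_activating_map())
  planted <- unique(lib$protein_change[lib$true_activity > 1])
  for (seed in 1:2) {
    cfg <- selection_config(depth_per_round = 1e5, seed = seed,
                            pcr_error_rate = 1.2e-3)
    tab <- simulate_screen(lib, cfg)
    freqs <- compute_frequencies(tab)
    acts <- c("actA_r2", "actB_r2")
    f12 <- intersect(filter_frequency(freqs, acts),
                     filter_fold_enrichment(freqs, acts, "lof_r2"))
    pc <- freqs$protein_change[match(f12,
                                     paste(freqs$nt_pos, freqs$ref,
                                           freqs$alt, sep = ":"))]
    expect_setequal(pc, planted)
  }
})

test_that("coverage_qc flags means, positions and degenerate input", {
  v <- data.frame(nt_pos = 1:2, ref = "A", alt = "G",
                  protein_change = c("A1V", "A1E"))
  cov <- matrix(120000L, 2, 1, dimnames = list(1:2, "act"))
  tab <- variant_count_table(v, cbind(act = c(5L, 5L)), cov)
  qc <- coverage_qc(tab, mean_min = 1e5, per_position_min = 4e4)
  expect_true(qc$pass)

  cov2 <- cov; cov2[2, 1] <- 39999L
  tab2 <- variant_count_table(v, cbind(act = c(5L, 5L)), cov2)
  qc2 <- coverage_qc(tab2, 1e5, 4e4)
  expect_false(qc2$pass)
  expect_equal(attr(qc2, "failing_positions")$act, 2L)

  empty <- variant_count_table(v[0, ],
                               matrix(integer(), 0, 1,
                                      dimnames = list(NULL, "act")),
                               matrix(integer(), 0, 1,
                                      dimnames = list(NULL, "act")))
  qc3 <- coverage_qc(empty)
  expect_equal(nrow(qc3), 0L)
  expect_false(attr(qc3, "valid"))
})
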