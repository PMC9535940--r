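test_that("coding_sequence validates its invariants", {
  expect_error(coding_sequence("ATGX"), "A, C, G, T")
  expect_error(coding_sequence("ATGC"), "multiple of 3")
  expect_error(coding_sequence("ATGTAACCC"), "internal stop")
  expect_silent(coding_sequence("ATGCCCTAA"))  # terminal stop is fine
  cds <- random_coding_sequence(50, seed = 1)
  expect_equal(cds_length(cds), 150L)
})

test_that("enumerate_snv_library is exhaustive, distinct, and consistent with
           a brute-force translation oracle", {
  cds <- coding_sequence("ATG")
  expect_equal(nrow(enumerate_snv_library(cds)), 9L)

  for (seed in 1:3) {
    cds <- random_coding_sequence(10, seed = seed)  # 30 nt -> 90 variants
    lib <- enumerate_snv_library(cds)
    expect_equal(nrow(lib), 3L * cds_length(cds))
    expect_false(anyDuplicated(paste(lib$nt_pos, lib$alt)) > 0)
    expect_setequal(paste(lib$nt_pos, lib$ref, lib$alt),
                    with(oracle_enumerate(cds), paste(nt_pos, ref, alt)))
    # every protein label consistent with full-sequence translation
    for (i in seq_len(nrow(lib))) {
      aa <- oracle_translate_variant(cds, lib$nt_pos[i], lib$alt[i])
      expect_equal(substr(aa, lib$codon_index[i], lib$codon_index[i]),
                   lib$alt_aa[i])
    }
    wt_aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds$nucleotides), no.init.codon = TRUE))
    expect_equal(sum(lib$synonymous),
                 sum(vapply(seq_len(nrow(lib)), function(i) {
                   identical(oracle_translate_variant(cds, lib$nt_pos[i],
                                                      lib$alt[i]), wt_aa)
                 }, logical(1))))
  }
})

test_that("assign_activities plants the mapped truth and reports skips", {
  cds <- random_coding_sequence(5, seed = 2, numbering_offset = 856,
                                fixed_codons = c("858" = "CTG"))
  lib <- enumerate_snv_library(cds)

  out <- assign_activities(lib, numeric())
  expect_true(all(out$true_activity == 1))

  out <- assign_activities(lib, c(L858R = 5.0))
  hit <- out$true_activity == 5.0
  expect_true(any(hit))
  expect_true(all(out$protein_change[hit] == "L858R"))
  # oracle: Arg codons reachable from CTG by one substitution = CGG only
  expect_equal(sum(hit), 1L)
  expect_equal(out$nt_pos[hit], (858 - 856) * 3 + 2)

  out <- assign_activities(lib, c(L858R = 0.0))  # loss of function allowed
  expect_equal(out$true_activity[out$protein_change == "L858R"], 0.0)

  expect_warning(out <- assign_activities(lib, c(W999F = 2)),
                 "not reachable")
  expect_equal(attr(out, "skipped_keys"), "W999F")
})

test_that("selection enriches active variants as the closed-form model
           predicts, and is neutral at stringency 1", {
  cds <- random_coding_sequence(20, seed = 3)  # 60 nt, 180 variants
  lib <- enumerate_snv_library(cds)
  target <- 7L
  lib$true_activity[target] <- 10

  cfg <- selection_config(rounds = 2, gate_stringency = 0.05,
                          depth_per_round = 1e6, seed = 4)
  tab <- simulate_selection_counts(lib, cfg)
  depth <- cfg$depth_per_round
  f <- as.matrix(as.data.frame(tab)[c("input", "act_r1", "act_r2")]) / depth
  expect_lt(f[target, 1], f[target, 2])
  expect_lt(f[target, 2], f[target, 3])

  # closed-form expectation, checked within 3 binomial SDs
  s <- -log(cfg$gate_stringency)
  q <- rep(cfg$library_mutant_fraction / nrow(lib), nrow(lib))
  w <- pmax(lib$true_activity, 1e-6)^s
  for (r in 1:2) {
    q <- q * w / (sum(q * w) + (1 - sum(q)))
    sd_bin <- sqrt(q[target] * (1 - q[target]) / depth)
    expect_lt(abs(f[target, r + 1] - q[target]), 3 * sd_bin)
  }

  # stringency 1 with equal activities: frequencies unchanged in expectation
  lib$true_activity[] <- 1
  cfg1 <- selection_config(rounds = 2, gate_stringency = 1,
                           depth_per_round = 1e5, seed = 5)
  tab1 <- simulate_selection_counts(lib, cfg1)
  f0 <- tab1$input / 1e5
  f2 <- tab1$act_r2 / 1e5
  q0 <- cfg1$library_mutant_fraction / nrow(lib)
  expect_true(all(abs(f2 - f0) < 5 * sqrt(2 * q0 / 1e5)))
})

test_that("selection counts are bit-reproducible under a fixed seed", {
  lib <- enumerate_snv_library(random_coding_sequence(10, seed = 6))
  cfg <- selection_config(depth_per_round = 1e4, seed = 7)
  expect_identical(simulate_selection_counts(lib, cfg),
                   simulate_selection_counts(lib, cfg))
  t1 <- simulate_flow_events(2, 100, seed = 8)
  t2 <- simulate_flow_events(2, 100, seed = 8)
  expect_identical(t1, t2)
  w1 <- simulate_work_samples(-5, 2, 50, seed = 9)
  expect_identical(w1, simulate_work_samples(-5, 2, 50, seed = 9))
  d1 <- simulate_helix_dimer("N", 5, seed = 10)
  d2 <- simulate_helix_dimer("N", 5, seed = 10)
  expect_identical(d1$coords, d2$coords)
})

test_that("neutral selection passes a Kolmogorov-Smirnov drift check over
           20 seeds", {
  lib <- enumerate_snv_library(random_coding_sequence(50, seed = 11))
  p_values <- vapply(1:20, function(seed) {
    cfg <- selection_config(rounds = 2, gate_stringency = 0.3,
                            depth_per_round = 1e5, seed = 100 + seed)
    tab <- simulate_selection_counts(lib, cfg)
    suppressWarnings(
      stats::ks.test(tab$input / 1e5, tab$act_r2 / 1e5)$p.value)
  }, numeric(1))
  expect_true(all(p_values > 0.01))
})

test_that("apply_pcr_noise adds biased artifacts and conserves coverage", {
  cds <- coding_sequence(paste(rep("TGC", 10), collapse = ""))  # C every 3rd
  lib <- enumerate_snv_library(cds)
  cfg0 <- selection_config(rounds = 0, depth_per_round = 1e5, seed = 12,
                           pcr_error_rate = 0)
  tab <- simulate_selection_counts(lib, cfg0)

  expect_identical(apply_pcr_noise(tab, cfg0), tab)  # rate 0 is a no-op

  cfg <- selection_config(rounds = 0, depth_per_round = 1e5, seed = 12,
                          pcr_error_rate = 1e-3, ct_bias_factor = 10)
  noisy <- apply_pcr_noise(tab, cfg)

  ct <- noisy$ref == "C" & noisy$alt == "T"
  added <- noisy$input - tab$input
  # expected artifact counts ~ coverage * rate (wild type dominates):
  # 1000 for C->T, 100 otherwise, each within 3 binomial SDs
  expect_true(all(abs(added[ct] - 1000) < 3 * sqrt(1e5 * 1e-2)))
  expect_true(all(abs(added[!ct] - 100) < 3 * sqrt(1e5 * 1e-3)))

  # coverage conservation: per position, alt counts never exceed coverage
  # and the coverage table itself is untouched
  expect_identical(attr(noisy, "coverage"), attr(tab, "coverage"))
  per_pos <- tapply(noisy$input, noisy$nt_pos, sum)
  expect_true(all(per_pos <= 1e5))

  bad <- selection_config(pcr_error_rate = 0.4, ct_bias_factor = 1)
  expect_error(apply_pcr_noise(tab, bad), "sum to > 1")
  expect_error(selection_config(pcr_error_rate = 0.2, ct_bias_factor = 10),
               "exceeds 1")
})

test_that("flow generator reproduces its closed forms", {
  p <- flow_sim_params()
  e <- rlnorm(2e4, p$expr_meanlog, p$expr_sdlog)
  wt <- simulate_flow_events(1, 2e4, seed = 13, expression = e)
  act <- simulate_flow_events(5, 2e4, seed = 14, expression = e)
  # matched expression: median phospho ratio ~ 5 (background shifts it
  # slightly below; tolerance 5%)
  expect_equal(median(act$phospho) / median(wt$phospho), 5, tolerance = 0.05)

  bg <- simulate_flow_events(n_events = 2e4, seed = 15, transfected = FALSE)
  expect_lt(abs(cor(log(bg$expression), log(bg$phospho))), 0.02)

  expect_error(simulate_flow_events(1, 0), "positive")
})

test_that("the diagonal-gated wild-type fraction grows with expression", {
  gate <- diagonal_gate(1, log10(0.2 * 3), side = "above")
  knee <- qlnorm(0.8, log(1000), 1)  # fixed receptor-density knee
  fracs <- vapply(c(500, 1000, 2000), function(med) {
    p <- flow_sim_params(expr_meanlog = log(med), knee = knee)
    ev <- simulate_flow_events(1, 1e5, seed = 16, params = p)
    nrow(gate_diagonal(ev, gate)) / nrow(ev)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("work-sample generator matches its stated moments", {
  ws <- simulate_work_samples(-10, 0, 25, seed = 17)
  expect_true(all(ws$forward == -10))  # sigma 0: all samples equal dG

  kT <- boltzmann_kT()
  expect_equal(kT, 2.577, tolerance = 1e-3)
  ws <- simulate_work_samples(-49.2, 5, 2e5, kT = kT, seed = 18)
  shift <- 25 / (2 * kT)
  se <- 5 / sqrt(2e5)
  expect_lt(abs(mean(ws$forward) - (-49.2 + shift)), 3 * se)
  # Crooks consistency: mean(W_f) + mean(W_r) -> sigma^2 / kT
  expect_lt(abs(mean(ws$forward) + mean(ws$reverse) - 25 / kT),
            3 * sqrt(2) * se)
  expect_error(simulate_work_samples(0, 1, 10, kT = 0), "positive")
})

test_that("helix-dimer fixtures have the stated pose geometry", {
  for (pose in c("N", "C")) {
    trj <- simulate_helix_dimer(pose, n_frames = 25, seed = 19)
    d_n <- min_motif_distance(trj, trj$motifs$tgmvga, trj$motifs$tgmvga)
    d_c <- min_motif_distance(trj, trj$motifs$algig, trj$motifs$algig)
    if (pose == "N") {
      expect_true(all(d_n < 0.6))
      expect_true(all(d_c > 1.0))
      expect_true(all(d_n < d_c))
    } else {
      expect_true(all(d_c < 0.6))
      expect_true(all(d_n > 1.0))
    }
  }
})

test_that("hydrogen-bond frames are deterministic and exact", {
  trj <- simulate_helix_dimer("C", n_frames = 1000, hbond_fraction = 0.5,
                              variant = "L658Q", seed = 20)
  expect_identical(sum(trj$hbond_frames), 500L)
  expect_equal(hbond_occupancy(trj), 0.5)
  expect_error(simulate_helix_dimer("C", 10, hbond_fraction = 1.5),
               "\\[0, 1\\]")
  expect_error(simulate_helix_dimer("C", 10, hbond_fraction = 0.5,
                                    variant = "wt"), "Gln")
})

test_that("chain swap leaves the contact map invariant (symmetric
           placement)", {
  trj <- simulate_helix_dimer("C", n_frames = 4, seed = 21)
  cm <- contact_distance_map(trj)
  swapped <- trj
  swapped$atoms$chain <- ifelse(trj$atoms$chain == "A", "B", "A")
  cm_swapped <- contact_distance_map(swapped)
  expect_lt(max(abs(cm - t(cm_swapped))), 1e-9)
})
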