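test_that("every generator is a pure function of its seed", {
  expect_identical(gen_emsa_data(0.8, 5, noise_sd = 0.05, n_replicates = 3,
                                 seed = 41),
                   gen_emsa_data(0.8, 5, noise_sd = 0.05, n_replicates = 3,
                                 seed = 41))
  expect_identical(gen_codon_alignment(20, n_seqs = 8, syn_rate = 0.1,
                                       nonsyn_rate = 0.1, seed = 41),
                   gen_codon_alignment(20, n_seqs = 8, syn_rate = 0.1,
                                       nonsyn_rate = 0.1, seed = 41))
  expect_identical(gen_gene_table(200, 10, seed = 41),
                   gen_gene_table(200, 10, seed = 41))
  expect_identical(gen_competition(0.1, seed = 41),
                   gen_competition(0.1, seed = 41))
  expect_identical(gen_ffl_timecourse(ffl_params(), obs_noise_sd = 0.1,
                                      seed = 41),
                   gen_ffl_timecourse(ffl_params(), obs_noise_sd = 0.1,
                                      seed = 41))
})

test_that("noise-free EMSA tables lie exactly on the binding curve", {
  d <- gen_emsa_data(0.8, 5, noise_sd = 0)[[1]]
  expect_equal(d$dose_ug, c(0, 1, 5, 10, 15, 20))  # six-dose default
  expect_equal(d$fraction_bound, predict_fraction(0.8, 5, d$dose_ug))
  expect_error(gen_emsa_data(1.2, 5), "frmax")
  expect_error(gen_emsa_data(0.8, -1), "kx")
  expect_error(gen_emsa_data(0.8, 5, noise_sd = -0.1), "noise_sd")
})

test_that("codon alignment generator honours rates and windows", {
  # all rates zero: clones of the ancestor, flat profile
  aln0 <- gen_codon_alignment(15, n_seqs = 5, syn_rate = 0, nonsyn_rate = 0,
                              seed = 42)
  expect_equal(length(unique(aln0$sequences)), 1L)
  prof0 <- dnds_profile(aln0)
  expect_true(all(prof0$dN == 0))
  # default emulates the 42-isolate alignment
  expect_equal(length(gen_codon_alignment(10, seed = 1)$ids), 42L)
  # purifying window: nonsynonymous changes forbidden inside
  aln <- gen_codon_alignment(40, n_seqs = 42, syn_rate = 0.05,
                             nonsyn_rate = 0.15,
                             constrained_window = 11:25,
                             window_nonsyn_rate = 0, seed = 43)
  prof <- dnds_profile(aln)
  expect_true(all(prof$dN[11:25] == 0, na.rm = TRUE))
  expect_gt(mean(prof$dN[-(11:25)], na.rm = TRUE), 0)
  # no stop codons anywhere
  for (s in aln$sequences) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(Biostrings::GENETIC_CODE[cods] == "*"))
  }
  expect_error(gen_codon_alignment(10, syn_rate = 1), "rates")
  expect_error(gen_codon_alignment(10, constrained_window = 5:12), "window")
})

test_that("gene table generator controls the focal correlation", {
  gt <- gen_gene_table(500, 20, true_corr = 1, noise_sd = 0, seed = 44)
  expect_equal(cor(gt$affinity[gt$is_target], gt$lfc[gt$is_target],
                   method = "spearman"), 1)
  gt2 <- gen_gene_table(seed = 45)   # study-scale defaults
  expect_equal(nrow(gt2), 6000L)
  expect_equal(sum(gt2$is_target), 41L)
  expect_error(gen_gene_table(true_corr = 1.5), "true_corr")
  expect_error(gen_gene_table(100, 100), "n_target")
})

test_that("competition generator inverts exactly in the no-sampling limit", {
  tc <- gen_competition(0.1, depth = Inf)
  est <- suppressWarnings(estimate_fitness(tc))
  expect_equal(est$s, 0.1, tolerance = 1e-12)
  tc0 <- gen_competition(0, depth = Inf)
  expect_equal(tc0$count_query / tc0$count_reference,
               rep(1 / 9, nrow(tc0)), tolerance = 1e-12)
  # binomial mode keeps the 1:9 mixing and 10,000-cell defaults
  tc_b <- gen_competition(0.1, seed = 46)
  expect_equal(tc_b$count_query + tc_b$count_reference,
               rep(10000, nrow(tc_b)))
  # runaway selection saturates the assay: generator warns, estimation
  # rejects the resulting zero counts
  expect_warning(tc_x <- gen_competition(5, generation_points = c(0, 50, 100),
                                         depth = 100, seed = 48),
                 "frequency")
  expect_error(estimate_fitness(tc_x), "non-positive count")
})

test_that("FFL timecourse noise touches observations, never dynamics", {
  p <- ffl_params(1, 0.4, 2, 1)
  clean <- gen_ffl_timecourse(p, obs_noise_sd = 0)
  noisy <- gen_ffl_timecourse(p, obs_noise_sd = 0.05, seed = 47)
  expect_equal(attr(noisy, "truth")[, c("dal80", "mep2")],
               clean[, c("dal80", "mep2")], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(noisy$mep2, clean$mep2)))
  # long-time sample approaches the analytic steady state
  late <- gen_ffl_timecourse(p, obs_noise_sd = 0, sample_times = 60)
  expect_equal(late$mep2, 0.2, tolerance = 1e-6)
})

test_that("generator output validates against consumer contracts across seeds", {
  for (seed in 1:10) {
    d <- gen_emsa_data(0.7, 4, noise_sd = 0.03, seed = seed)[[1]]
    expect_s3_class(d, "dose_response")
    aln <- gen_codon_alignment(10, n_seqs = 6, syn_rate = 0.1,
                               nonsyn_rate = 0.1, seed = seed)
    expect_s3_class(aln, "codon_alignment")
    expect_s3_class(gen_gene_table(100, 5, seed = seed), "gene_table")
    expect_s3_class(gen_competition(0.05, seed = seed),
                    "competition_timecourse")
  }
})
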