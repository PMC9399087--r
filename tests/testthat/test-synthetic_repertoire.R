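test_that("generation is deterministic: same seed, byte-identical output", {
  p <- lineage_profile(n_clones = 300)
  s1 <- generate_sample(p, seed = 5, sample_id = "d")
  s2 <- generate_sample(p, seed = 5, sample_id = "d")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_airr(s1, f1); write_airr(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- generate_sample(p, seed = 6, sample_id = "d")
  expect_false(identical(s1$cdr3_nt, s3$cdr3_nt))
})

test_that("generated clone tables satisfy the data-model invariants", {
  s <- generate_sample(lineage_profile(n_clones = 500), seed = 3)
  expect_equal(anyDuplicated(s[, c("v_gene", "cdr3_nt")]), 0)
  expect_true(all(s$detection_count >= 1))
  expect_equal(nchar(s$cdr3_aa), nchar(s$junction_aa) - 2L)
  expect_true(all(nchar(s$cdr3_nt) == 3 * nchar(s$junction_aa)))
  # back-translation is faithful: junctions translate back to junction_aa
  tr <- vapply(seq_len(20), function(i) {
    codons <- substring(s$cdr3_nt[i],
                        seq(1, nchar(s$cdr3_nt[i]), 3),
                        seq(3, nchar(s$cdr3_nt[i]), 3))
    paste(vapply(codons, function(cd) {
      seqinr::translate(strsplit(cd, "")[[1]])
    }, character(1)), collapse = "")
  }, character(1))
  expect_equal(tr, s$junction_aa[1:20])
})

test_that("the forced apex-Cys rate is recovered when background Cys is off", {
  p <- lineage_profile(n_clones = 5000, apex_cys_prob = 0.08,
                       singleton_fraction = 0,
                       residue_freq = residue_frequencies(0),
                       trbv1_germline_cys = FALSE)
  s <- generate_sample(p, seed = 17)
  r <- cysteine_index(s)
  # central 99% binomial interval for p = 0.08, n = n_eligible
  ci <- qbinom(c(0.005, 0.995), r$n_eligible, 0.08) / r$n_eligible * 100
  expect_gte(r$index_percent, ci[1])
  expect_lte(r$index_percent, ci[2])
  # and the package agrees exactly with the brute-force oracle
  oracle <- oracle_cys_index(tibble::as_tibble(s))
  expect_equal(r$index_percent, oracle$index_percent)
})

test_that("zero apex probability and zero background force the fallback", {
  p <- lineage_profile(n_clones = 200, apex_cys_prob = 0,
                       singleton_fraction = 0,
                       residue_freq = residue_frequencies(0),
                       trbv1_germline_cys = FALSE)
  r <- cysteine_index(generate_sample(p, seed = 8))
  expect_true(r$zero_fallback_used)
  expect_equal(r$index_percent, 100 / r$n_eligible)
})

test_that("index bias shrinks as samples grow (parameter recovery)", {
  bias_at <- function(n, seeds) {
    errs <- vapply(seeds, function(sd) {
      p <- lineage_profile(n_clones = n, apex_cys_prob = 0.06,
                           singleton_fraction = 0.1,
                           residue_freq = residue_frequencies(0),
                           trbv1_germline_cys = FALSE)
      cysteine_index(generate_sample(p, seed = sd))$index_percent - 6
    }, numeric(1))
    abs(mean(errs))
  }
  expect_lt(bias_at(5000, 1:8), bias_at(500, 1:8) + 0.35)
  expect_lt(bias_at(5000, 1:8), 0.35)
})

test_that("singleton and doubleton clones never move the index", {
  p <- lineage_profile(n_clones = 800, apex_cys_prob = 0.05,
                       singleton_fraction = 0.4)
  s <- generate_sample(p, seed = 21)
  r_all <- cysteine_index(s)
  trimmed <- s[s$detection_count >= 3, ]
  r_trim <- cysteine_index(
    repertoire_sample(tibble::as_tibble(trimmed), sample_id = "t",
                      chain = attr(s, "chain")))
  expect_equal(r_all$index_percent, r_trim$index_percent)
})

test_that("the Trbv1 exclusion removes germline-Cys clones directionally", {
  # a Trbv1-heavy, short-CDR3 profile: many germline position-2 Cys clones
  # sit inside the apex window and are stripped by the rule
  short_lengths <- setNames(rep(0, 17), 4:20)
  short_lengths[as.character(4:7)] <- 0.25
  p <- lineage_profile(
    n_clones = 1500, apex_cys_prob = 0,
    cdr3_length_distribution = short_lengths,
    v_gene_usage = setNames(c(0.6, 0.4), c("TRBV1", "TRBV2")),
    residue_freq = residue_frequencies(0),
    singleton_fraction = 0
  )
  s <- generate_sample(p, seed = 12)
  with_rule <- cysteine_index(s)$index_percent
  without_rule <- cysteine_index(s, trbv1_min_len = 0)$index_percent
  expect_gt(without_rule, with_rule)
})

test_that("a study emits the configured design and manifest", {
  cfg <- study_config(n_mice_per_group = 2, seed = 33, n_clones = 300)
  st <- generate_study(cfg)
  expect_length(st$samples, 4 * 2)  # lineages x mice
  expect_equal(nrow(st$manifest), 8)
  expect_equal(sort(unique(st$manifest$lineage)),
               sort(names(cfg$profiles)))
  # attenuated genotype flattens the apex-Cys probabilities
  flat <- study_config(genotype_effect = "signaling_attenuated",
                       n_mice_per_group = 2, seed = 33, n_clones = 300)
  expect_equal(unique(vapply(flat$profiles, `[[`, numeric(1),
                             "apex_cys_prob")),
               cfg$profiles$preselection$apex_cys_prob)
})
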