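test_that("classification extracts the planted events of constructed reads", {
  t <- fixture_amplicon("ACGT")
  expect_identical(nrow(classify_errors(make_read("ACGT"), t)), 0L)
  ev <- classify_errors(make_read("ACAT"), t)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "sub")
  expect_identical(ev$pos, 3L)
  expect_identical(ev$ref_base, "G")
  expect_identical(ev$read_base, "A")
  expect_identical(ev$change, "G>A")
  # same mismatch on a minus-strand consensus tallies as the complement
  evm <- classify_errors(make_read("ACAT", strand = "-"), t)
  expect_identical(evm$change, "C>T")
  expect_error(classify_errors(make_read("ACGT", ref = "nope"), t),
               "unknown")
})

test_that("classification agrees with simulator truth for planted indels", {
  ref <- strrep("ACGTG", 8)
  t <- fixture_amplicon(ref)
  # delete ref 11, insert "T" after ref 20, substitute ref 30
  seq <- paste0(substr(ref, 1, 10), substr(ref, 12, 20), "T",
                substr(ref, 21, 29), "A", substr(ref, 31, 40))
  rd <- make_read(seq, cigar = "10M1D9M1I19M")
  ev <- classify_errors(rd, t)
  ev <- ev[order(ev$pos), ]
  expect_identical(ev$kind, c("del", "ins", "sub"))
  expect_identical(ev$pos, c(11L, 20L, 30L))
  expect_identical(ev$read_base, c("-", "T", "A"))
})

test_that("composition-averaged rates match the hand-computed example", {
  subs <- stats::setNames(integer(12), pcrfidelity:::SUB_TYPES)
  subs["A>G"] <- 2L; subs["C>T"] <- 1L
  cnt <- error_counts(N_A = 1000, N_T = 1000, N_G = 500, N_C = 500,
                      subs = subs)
  sr <- substitution_rate(cnt)
  expect_equal(sr$e_AT, 2 / 2000)
  expect_equal(sr$e_GC, 1 / 1000)
  expect_equal(sr$e, 1e-3)
  expect_equal(substitution_rate(cnt, "plain"), 3 / 3000)

  zero <- error_counts(N_A = 250000, N_T = 250000, N_G = 250000,
                       N_C = 250000)
  expect_equal(substitution_rate(zero)$e, 0)
  expect_error(substitution_rate(error_counts()), "undefined")
})

test_that("indel rates divide event counts by analyzed bases", {
  cnt <- error_counts(N_A = 2.5e6, N_T = 2.5e6, N_G = 2.5e6, N_C = 2.5e6,
                      N_deletion = 24, N_insertion = 0)
  ir <- indel_rates(cnt)
  expect_equal(ir$e_del, 2.4e-6)
  expect_equal(ir$e_ins, 0)
  cnt2 <- error_counts(N_A = 2.5e5, N_T = 2.5e5, N_G = 2.5e5, N_C = 2.5e5,
                       N_deletion = 100)
  expect_equal(indel_rates(cnt2)$e_del, 1e-4)
  expect_error(indel_rates(error_counts()), "undefined")
})

test_that("doublings derive from yield and Eq-6 normalization round-trips", {
  expect_equal(doublings_from_yield(100, 100), 0)
  expect_equal(doublings_from_yield(1024, 1), 10)
  expect_equal(doublings_from_yield(1500, 100), log2(15))
  expect_equal(doublings_from_yield(1500, 100), 3.9069, tolerance = 1e-4)
  expect_error(doublings_from_yield(50, 100), "below input")
  expect_error(doublings_from_yield(10, 0), "positive")

  expect_equal(normalize_per_doubling(0, 10), 0)
  expect_equal(normalize_per_doubling(1e-3, 10), 2e-4)
  expect_error(normalize_per_doubling(1e-3, 0), "positive")
  # algebraic identity: normalize(propagate(e, n), n) = e
  set.seed(1)
  for (k in 1:20) {
    e <- 10^stats::runif(1, -7, -3)
    n <- stats::runif(1, 0.5, 20)
    expect_equal(normalize_per_doubling(n * e / 2, n), e)
  }
})

test_that("per-cycle conversion reproduces the published damage arithmetic", {
  expect_equal(signif(per_cycle_rate(2.3e-5, 16), 2), 1.4e-6)
  expect_equal(per_cycle_rate(0, 16), 0)
  expect_equal(per_cycle_rate(1.6e-3, 16), 1e-4)
  expect_error(per_cycle_rate(1e-3, 0), "positive")
})

test_that("spectrum tallies merge complementary pairs and sum to 100", {
  subs <- stats::setNames(integer(12), pcrfidelity:::SUB_TYPES)
  subs[c("A>G", "T>C")] <- 50L
  sp <- mutational_spectrum(subs)
  expect_equal(unname(sp$pairs["A>G/T>C"]), 100)
  expect_equal(sum(sp$pairs), 100)

  subs <- stats::setNames(integer(12), pcrfidelity:::SUB_TYPES)
  subs["A>G"] <- 33L; subs["T>C"] <- 33L; subs["G>A"] <- 19L
  subs["A>T"] <- 9L
  subs[c("A>C", "G>C", "G>T")] <- 2L
  sp <- mutational_spectrum(subs)
  expect_equal(unname(sp$pairs["A>G/T>C"]), 66)
  expect_equal(unname(sp$pairs["G>A/C>T"]), 19)
  expect_equal(unname(sp$pairs["A>T/T>A"]), 9)
  expect_equal(sum(sp$pairs), 100, tolerance = 1e-9)
  expect_error(mutational_spectrum(error_counts()), "no substitution")
})

test_that("the estimator recovers configured per-doubling rates", {
  t <- fixture_homolog_pair()
  for (e in c(5e-6, 1.5e-4, 5e-4)) {
    cfg <- simulation_config(seed = round(1e6 * e) + 17, n_reads = 6000,
                             sub_rate_per_doubling = e,
                             target_doublings = 10)
    sim <- simulate_amplification(t, cfg)
    fit <- estimate_error_rates(sim$reads, t, doublings = 10)
    events <- sum(fit$counts$subs)
    se_rel <- 1 / sqrt(max(events, 1))
    expect_lt(abs(fit$rates$e_normalized - e) / e, 3 * se_rel + 1e-12)
    expect_equal(fit$rates$accuracy, 1 / fit$rates$e_sub)
  }
})

test_that("composition averaging equals plain division on balanced data", {
  t <- fixture_homolog_pair()
  cfg <- simulation_config(seed = 77, n_reads = 4000,
                           sub_rate_per_doubling = 3e-4,
                           target_doublings = 10)
  sim <- simulate_amplification(t, cfg)
  fit_a <- estimate_error_rates(sim$reads, t, doublings = 10)
  fit_p <- estimate_error_rates(sim$reads, t, doublings = 10,
                                mode = "plain")
  expect_equal(fit_a$rates$e_sub, fit_p$rates$e_sub, tolerance = 1e-3)
})

test_that("event-quality and primer masking shape the counted events", {
  ref <- strrep("ACGTG", 10)
  t <- fixture_amplicon(ref, primer = data.frame(start = 1, end = 5))
  seq <- ref
  substr(seq, 3, 3) <- "T"    # inside the primer mask
  substr(seq, 30, 30) <- "A"  # counted
  q <- strrep("~", 50); substr(q, 30, 30) <- "!"  # QV 0 at position 30
  rd <- rbind(make_read(seq, read_id = "good"),
              make_read(seq, read_id = "lowq", qual = q))
  fit <- estimate_error_rates(rd, t, doublings = 10)
  # good read: primer event masked, one counted sub; lowq read: the
  # position-30 event fails the QV-93 requirement
  expect_identical(sum(fit$counts$subs), 1L)
  expect_identical(fit$masked_events, 2L)
  # masked positions leave the denominator symmetrically
  expect_equal(fit$counts$N, 2 * (50 - 5))
})
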