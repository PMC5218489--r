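test_that("marker calling demands the allele plus matching flanks", {
  t <- fixture_homolog_pair()
  refA <- t$sequences[["homolog-A"]]
  refB <- t$sequences[["homolog-B"]]
  mk <- t$markers
  expect_identical(call_markers(make_read(refA), mk, refA),
                   rep("A", nrow(mk)))
  expect_identical(call_markers(make_read(refB), mk, refA),
                   rep("B", nrow(mk)))
  # substitution in a flanking base invalidates only that marker
  seq <- refA
  p <- mk$position[3] + 1L
  substr(seq, p, p) <- setdiff(c("A", "C", "G", "T"),
                               substr(seq, p, p))[1]
  v <- call_markers(make_read(seq), mk, refA)
  expect_identical(v[3], "invalid")
  expect_identical(v[-3], rep("A", nrow(mk) - 1L))
  # a non-allelic base at the marker itself is invalid
  seq2 <- refA
  p2 <- mk$position[5]
  other <- setdiff(c("A", "C", "G", "T"),
                   c(mk$allele_a[5], mk$allele_b[5]))[1]
  substr(seq2, p2, p2) <- other
  expect_identical(call_markers(make_read(seq2), mk, refA)[5], "invalid")
  # a deletion spanning a marker is invalid
  p5 <- mk$position[5]
  del <- paste0(substr(refA, 1, p5 - 1L), substr(refA, p5 + 1L, 1100))
  rd <- make_read(del, cigar = sprintf("%dM1D%dM", p5 - 1L, 1100 - p5))
  v <- call_markers(rd, mk, refA)
  expect_identical(v[5], "invalid")
  expect_identical(v[-5], rep("A", nrow(mk) - 1L))
  expect_error(call_markers(make_read(refA), marker_table(5000, "A", "C"),
                            refA),
               "outside")
})

test_that("switch counting matches a brute-force oracle", {
  expect_identical(count_switches(rep("A", 5)), 0L)
  expect_identical(count_switches(c("A", "A", "A", "B", "B")), 1L)
  expect_identical(count_switches(c("A", "B", "A")), 2L)
  expect_identical(count_switches(c("A", "invalid", "B")), 1L)
  expect_identical(count_switches(c("invalid", "A")), 0L)
  expect_identical(count_switches(character(0)), 0L)
  set.seed(42)
  for (k in 1:200) {
    v <- sample(c("A", "B", "invalid"), sample(1:12, 1), replace = TRUE)
    expect_identical(count_switches(v), brute_force_switches(v))
  }
})

test_that("rates double the detected events and normalize per doubling", {
  expect_equal(recombination_rate(0, 1e6, 10)$raw_rate, 0)
  rr <- recombination_rate(100, 1e6, 10)
  expect_equal(rr$raw_rate, 2e-4)
  expect_equal(rr$normalized_rate, 4e-5)
  # published-count arithmetic: 2 * 19,943 / 77,725,936
  rr2 <- recombination_rate(19943, 77725936, NA)
  expect_equal(rr2$raw_rate, 5.13e-4, tolerance = 1e-3)
  expect_error(recombination_rate(10, 0, 10), "no analyzed")
})

test_that("events land in the interval between flanking valid markers", {
  cm <- matrix(c("A", "A", "A", "B", "B"), nrow = 1)
  pid <- per_interval_distribution(cm)
  expect_identical(unname(pid), c(0L, 0L, 1L, 0L))
  cm2 <- matrix(c("A", "invalid", "B", "B", "B"), nrow = 1)
  expect_identical(unname(per_interval_distribution(cm2)),
                   c(1L, 0L, 0L, 0L))
  expect_identical(sum(per_interval_distribution(
    matrix("invalid", 3, 5))), 0L)
})

test_that("switch positions distribute evenly across intervals", {
  t <- fixture_homolog_pair()
  cfg <- simulation_config(seed = 31, n_reads = 8000,
                           target_doublings = 10,
                           recomb_rate_per_doubling = 4e-4,
                           read_pass_model = c(3L, 40L))
  sim <- simulate_amplification(t, cfg)
  rec <- scan_recombination(sim$reads, t, doublings = 10)
  expect_identical(sum(rec$per_interval), rec$N_re)
  # interior marker intervals are equal length, so detected events should
  # be uniform over them
  expect_gt(rec$N_re, 3000)
  p <- stats::chisq.test(rec$per_interval)$p.value
  expect_gt(p, 0.01)
})

test_that("cryptic switches halve detection in a 50:50 mix", {
  t <- fixture_homolog_pair()
  cfg <- simulation_config(seed = 23, n_reads = 10000,
                           target_doublings = 10.69,
                           recomb_rate_per_doubling = 9.6e-5,
                           read_pass_model = c(3L, 40L))
  sim <- simulate_amplification(t, cfg)
  truth_sw <- sim$truth[sim$truth$kind == "recomb_switch", ]
  cryptic <- sub(">.*", "", truth_sw$detail) ==
    sub(".*>", "", truth_sw$detail)
  # half the switch partners are the same template family
  expect_lt(abs(mean(cryptic) - 0.5), 3 * sqrt(0.25 / nrow(truth_sw)))
  rec <- scan_recombination(sim$reads, t, doublings = 10.69)
  # detected events are about half of truth (edge/parity censoring keeps
  # the ratio slightly below 1/2), so the doubled raw rate recovers the
  # truth per-base fraction
  ratio <- rec$N_re / nrow(truth_sw)
  expect_gt(ratio, 0.40)
  expect_lt(ratio, 0.52)
  expect_lt(abs(rec$normalized_rate - 9.6e-5) / 9.6e-5, 0.12)
})

test_that("identical co-amplified templates give zero detected events", {
  # single template family: every switch partner is identical, so truth
  # events continue at the configured rate but none are detectable
  set.seed(2)
  seq <- paste(sample(rep(c("A", "C", "G", "T"), 250)), collapse = "")
  t <- fixture_amplicon(seq)
  cfg <- simulation_config(seed = 29, n_reads = 2000,
                           target_doublings = 10,
                           recomb_rate_per_doubling = 4e-4,
                           read_pass_model = c(3L, 40L))
  sim <- simulate_amplification(t, cfg)
  expect_gt(sum(sim$truth$kind == "recomb_switch"), 1000)
  expect_true(all(sim$reads$sequence == seq))
})

test_that("the strand fraction follows the Poisson prediction", {
  expect_equal(fraction_with_event(integer(5)), 0)
  expect_equal(fraction_with_event(c(rep(1L, 23), rep(0L, 77))), 23)
  t <- fixture_homolog_pair()
  cfg <- simulation_config(seed = 37, n_reads = 8000,
                           target_doublings = 10,
                           recomb_rate_per_doubling = 3e-4,
                           read_pass_model = c(3L, 40L))
  sim <- simulate_amplification(t, cfg)
  rec <- scan_recombination(sim$reads, t, doublings = 10)
  m <- rec$N_re / rec$n_reads
  pred <- 100 * (1 - exp(-m))
  se <- 100 * sqrt(pred / 100 * (1 - pred / 100) / rec$n_reads)
  expect_lt(abs(rec$strands_with_event_pct - pred), 4 * se)
})
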