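test_that("the four references follow the element geometry", {
  ts <- fixture_structured()
  tpl <- ts$sequences[[1]]
  el <- ts$elements[[1]]
  quad <- build_inversion_references(tpl, el, flank = 30)
  a <- el$start - 30L; b <- el$end + 30L
  expect_identical(unname(quad$refs["correct"]), substr(tpl, a, b))
  # double differs from correct only inside the loop
  dc <- which(strsplit(quad$refs[["double"]], "")[[1]] !=
                strsplit(quad$refs[["correct"]], "")[[1]])
  loop_local <- (30L + el$stem_length + 1L):(30L + el$stem_length +
                                               el$loop_length)
  expect_true(all(dc %in% loop_local))
  expect_gt(length(dc), 0)
  expect_error(
    build_inversion_references(tpl, inverted_repeat_element(2000, 8, 5)),
    "outside")
})

test_that("noise-free products classify exactly, across elements and strands", {
  for (fix in list(fixture_structured(), fixture_small_element())) {
    tpl <- fix$sequences[[1]]
    el <- fix$elements[[1]]
    quad <- build_inversion_references(tpl, el)
    for (cls in c("correct", "single-top", "single-bottom", "double")) {
      rd <- make_inversion_read(tpl, el, cls)
      expect_identical(classify_inversion_reads(rd, quad), cls)
    }
    # verbatim reference sequences classify as themselves
    for (cls in names(quad$refs))
      expect_identical(classify_inversion_reads(quad$refs[[cls]], quad),
                       cls)
  }
})

test_that("a single mismatch in the matched span voids the call", {
  ts <- fixture_small_element()
  tpl <- ts$sequences[[1]]
  el <- ts$elements[[1]]
  quad <- build_inversion_references(tpl, el)
  rd <- make_inversion_read(tpl, el, "double")
  p <- el$start + el$stem_length + 2L
  old <- substr(rd, p, p)
  substr(rd, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  expect_identical(classify_inversion_reads(rd, quad), "unassigned")
})

test_that("degenerate elements with identical references are refused", {
  # palindromic loop: double product equals the correct product
  seq <- paste0(strrep("ACGTG", 6), "CCATG", "ACGT", "CATGG",
                strrep("TACGT", 6))
  el <- inverted_repeat_element(31, 5, 4)
  expect_error(build_inversion_references(seq, el, flank = 10),
               "not unique")
})

test_that("inversion percentages follow the call counts", {
  ts <- fixture_structured()
  cfg <- simulation_config(seed = 19, n_reads = 4000,
                           target_doublings = 10,
                           inversion_probs = c("single-bottom" = 0.010,
                                               "double" = 0.004),
                           read_pass_model = c(3L, 40L))
  sim <- simulate_amplification(ts, cfg)
  scan <- scan_inversions(sim$reads, ts)
  r <- inversion_rates(scan)
  truth_inv <- sum(sim$truth$kind == "inversion")
  detected <- r$single_top + r$single_bottom + r$double
  expect_identical(detected, truth_inv)
  expect_equal(r$pct_inversions, 100 * detected / 4000)
  # recovery within 3 binomial s.e. of the configured fraction
  p0 <- 0.014
  se <- sqrt(p0 * (1 - p0) / 4000)
  expect_lt(abs(detected / 4000 - p0), 3 * se)
  # zero-switch scan prints n.d.
  cfg0 <- simulation_config(seed = 20, n_reads = 50, target_doublings = 10)
  sim0 <- simulate_amplification(ts, cfg0)
  scan0 <- scan_inversions(sim0$reads, ts)
  expect_equal(inversion_rates(scan0)$pct_inversions, 0)
  expect_output(print(scan0), "n.d.")
  expect_error(scan_inversions(sim0$reads[0, ], ts) |> inversion_rates(),
               "no reads")
})
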