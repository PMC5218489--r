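test_that("zero-rate simulation reproduces templates verbatim", {
  t <- fixture_homolog_pair()
  cfg <- simulation_config(seed = 5, n_reads = 50, target_doublings = 10)
  sim <- simulate_amplification(t, cfg)
  expect_identical(nrow(sim$truth), 0L)
  expect_true(all(sim$reads$sequence ==
                    unname(t$sequences[sim$reads$ref])))
  expect_true(all(sim$reads$cigar == "1100M"))
  expect_true(all(sim$reads$mapq == 254L))
})

test_that("closed-form substitution load matches the propagation model", {
  # f = n*e/2 per base: e = 2e-4, n = 10, L = 1000 -> 1 substitution/read
  t <- fixture_amplicon(paste(rep(c("A", "C", "G", "T"), 250), collapse = ""))
  cfg <- simulation_config(seed = 8, n_reads = 50000,
                           sub_rate_per_doubling = 2e-4,
                           target_doublings = 10)
  sim <- simulate_amplification(t, cfg)
  m <- sum(sim$truth$kind == "sub") / 50000
  se <- sqrt(1 / 50000)   # Poisson mean 1 per read
  expect_lt(abs(m - 1.0), 3 * se)
})

test_that("simulation configs are validated", {
  expect_error(simulation_config(seed = 1, target_doublings = 10,
                                 efficiency_per_cycle = 0.9,
                                 n_cycles = 10, initial_molecules = 5),
               "not both")
  expect_error(simulation_config(seed = 1), "one must be given")
  bad <- uniform_spectrum() * 0.9
  expect_error(simulation_config(seed = 1, target_doublings = 10,
                                 sub_spectrum = bad),
               "sub_spectrum")
  expect_error(
    do.call(simulation_config, list(target_doublings = 10, seed = NULL)),
    "seed")
})

test_that("perfect-efficiency lineage doubles every cycle", {
  t <- fixture_homolog_pair()
  cfg <- simulation_config(seed = 2, n_reads = 10,
                           efficiency_per_cycle = 1.0, n_cycles = 4,
                           initial_molecules = 1)
  sim <- simulate_amplification(t, cfg)
  expect_identical(attr(sim, "final_molecules"), 16L)
  expect_equal(attr(sim, "doublings"), 4)
})

test_that("lineage and closed-form modes agree on the error fraction", {
  t <- fixture_homolog_pair()
  e <- 2e-4
  cfgL <- simulation_config(seed = 7, n_reads = 6000,
                            efficiency_per_cycle = 1.0, n_cycles = 10,
                            initial_molecules = 20,
                            sub_rate_per_doubling = e)
  simL <- simulate_amplification(t, cfgL)
  nL <- attr(simL, "doublings")
  expect_equal(nL, 10)
  fL <- sum(simL$truth$kind == "sub") / sum(nchar(simL$reads$sequence))
  cfgC <- simulation_config(seed = 7, n_reads = 6000,
                            target_doublings = 10,
                            sub_rate_per_doubling = e)
  simC <- simulate_amplification(t, cfgC)
  fC <- sum(simC$truth$kind == "sub") / sum(nchar(simC$reads$sequence))
  # shared-ancestry correlation inflates the lineage variance beyond
  # binomial, so the band is relative rather than 3 naive s.e.
  expect_lt(abs(fL - fC) / (10 * e / 2), 0.10)
})

test_that("ground truth is conserved: truth events equal observed mismatches", {
  t <- fixture_homolog_pair()
  for (seed in c(11, 12, 13)) {
    cfg <- simulation_config(seed = seed, n_reads = 400,
                             sub_rate_per_doubling = 5e-4,
                             del_rate_per_doubling = 5e-5,
                             ins_rate_per_doubling = 5e-5,
                             damage_rate_per_cycle = 1e-5, n_cycles = 16,
                             target_doublings = 10)
    sim <- simulate_amplification(t, cfg)
    ev <- classify_errors(sim$reads, t)
    indel_reads <- unique(sim$truth$read_id[sim$truth$kind %in%
                                              c("del", "ins")])
    mm <- sum(ev$kind == "sub" & !(ev$read_id %in% indel_reads))
    tr <- sum(sim$truth$kind %in% c("sub", "damage") &
                !(sim$truth$read_id %in% indel_reads))
    expect_identical(mm, tr)
    # indel events round-trip through classification too
    expect_identical(sum(ev$kind == "del"), sum(sim$truth$kind == "del"))
    expect_identical(sum(ev$kind == "ins"), sum(sim$truth$kind == "ins"))
  }
})

test_that("damage accumulates as 1-(1-d)^c without replication", {
  # a base deaminated twice is still one mutated base, so d is kept small
  # enough that double hits are negligible against the sampling band
  t <- make_plasmid_template(500, seed = 6)
  d <- 1e-4; c <- 16
  cfg <- simulation_config(seed = 9, n_reads = 2000, target_doublings = 0,
                           damage_rate_per_cycle = d, n_cycles = c)
  sim <- simulate_amplification(t, cfg)
  f_exp <- 1 - (1 - d)^c
  n_bases <- 2000 * 500
  f_obs <- sum(sim$truth$kind == "damage") / n_bases
  se <- sqrt(f_exp / n_bases)
  expect_lt(abs(f_obs - f_exp), 3 * se)
  # and the closed form is close to the linear approximation c*d
  expect_equal(f_exp, c * d, tolerance = 0.01)
})

test_that("realized event types follow the configured spectrum", {
  t <- fixture_homolog_pair()
  cfg <- simulation_config(seed = 14, n_reads = 8000,
                           sub_rate_per_doubling = 5e-4,
                           sub_spectrum = taq_spectrum(),
                           target_doublings = 10)
  sim <- simulate_amplification(t, cfg)
  subs <- sim$truth[sim$truth$kind == "sub", ]
  # truth details are reference-oriented; flip minus-strand events back
  chg <- ifelse(subs$strand == "-",
                chartr("ACGT", "TGCA", subs$detail), subs$detail)
  obs <- table(factor(chg, levels = pcrfidelity:::SUB_TYPES))
  expect_gt(sum(obs), 20000)
  p <- stats::chisq.test(obs, p = taq_spectrum())$p.value
  expect_gt(p, 0.01)
})

test_that("inversion products have the documented geometry", {
  ts <- fixture_small_element()
  tpl <- ts$sequences[[1]]
  el <- ts$elements[[1]]
  L <- nchar(tpl)
  expect_identical(make_inversion_read(tpl, el, "correct"), tpl)

  dbl <- make_inversion_read(tpl, el, "double")
  expect_identical(nchar(dbl), L)
  loop <- (el$start + el$stem_length):(el$start + el$stem_length +
                                         el$loop_length - 1)
  diffs <- which(strsplit(dbl, "")[[1]] != strsplit(tpl, "")[[1]])
  expect_true(all(diffs %in% loop))
  expect_identical(substring(dbl, min(loop), max(loop)),
                   revcomp(substring(tpl, min(loop), max(loop))))

  st <- make_inversion_read(tpl, el, "single-top")
  expect_identical(nchar(st),
                   2L * (el$start + el$stem_length - 1L) + el$loop_length)
  expect_false(nchar(st) == L)
  expect_error(make_inversion_read(tpl, el, "triple"), "unknown")
})

test_that("emitted files round-trip through SAM", {
  t <- fixture_homolog_pair()
  dir <- withr::local_tempdir()
  # empty simulation -> valid header-only SAM and empty FASTA
  cfg0 <- simulation_config(seed = 1, n_reads = 0, target_doublings = 10)
  sim0 <- simulate_amplification(t, cfg0)
  p0 <- emit_reads(sim0, t, dir, prefix = "empty")
  expect_true(all(startsWith(readLines(p0[["sam"]]), "@")))
  expect_identical(length(Biostrings::readDNAStringSet(p0[["fasta"]])), 0L)

  cfg <- simulation_config(seed = 3, n_reads = 60, target_doublings = 10,
                           sub_rate_per_doubling = 1e-3,
                           del_rate_per_doubling = 3e-4,
                           ins_rate_per_doubling = 1e-4)
  sim <- simulate_amplification(t, cfg)
  paths <- emit_reads(sim, t, dir)
  back <- read_consensus_sam(paths[["sam"]])
  o1 <- order(sim$reads$read_id); o2 <- order(back$read_id)
  expect_identical(back$sequence[o2], sim$reads$sequence[o1])
  expect_identical(back$cigar[o2], sim$reads$cigar[o1])
  expect_identical(back$n_passes[o2], sim$reads$n_passes[o1])
  # the edit operations reconstruct each read from the reference exactly:
  # classification of the re-read SAM equals classification of the
  # in-memory reads
  ev1 <- classify_errors(sim$reads, t)
  ev2 <- classify_errors(back, t)
  key <- function(e) paste(e$read_id, e$pos, e$kind, e$read_base)
  expect_setequal(key(ev2), key(ev1))
})
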