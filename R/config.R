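# Simulation configuration: a validated parameter list shared by the
# closed-form and lineage-explicit simulation modes.

uniform_spectrum <- function() {
  stats::setNames(rep(1 / 12, 12L), SUB_TYPES)
}

#' Build a 12-change directed spectrum from complementary-pair shares
#'
#' Polymerase spectra are usually reported as percentages of the six
#' complementary pairs (A→G/T→C, G→A/C→T, ...). This helper splits each pair
#' share equally between its two directed changes and normalizes to 1.
#'
#' @param pairs Named numeric vector; names from
#'   `c("A>G/T>C","G>A/C>T","A>T/T>A","A>C/T>G","G>C/C>G","G>T/C>A")`,
#'   values in any consistent unit (percent or fraction).
#' @return Named numeric vector of 12 directed weights summing to 1, in the
#'   canonical `A>C ... T>G` order.
#' @export
pair_spectrum <- function(pairs) {
  if (is.null(names(pairs)) || !all(names(pairs) %in% names(SPECTRUM_PAIRS)))
    stop("names(pairs) must be complementary-pair labels such as 'A>G/T>C'")
  w <- stats::setNames(numeric(12L), SUB_TYPES)
  for (nm in names(pairs)) {
    for (tp in SPECTRUM_PAIRS[[nm]]) w[tp] <- w[tp] + pairs[[nm]] / 2
  }
  if (sum(w) <= 0) stop("pair shares must sum to a positive value")
  w / sum(w)
}

#' Taq-like directed substitution spectrum
#'
#' Complementary-pair shares as measured for Taq DNA polymerase by
#' single-molecule consensus sequencing (A→G/T→C 66%, G→A/C→T 19%,
#' A→T/T→A 9.3%, A→C/T→G 2.0%, G→C/C→G 1.6%, G→T/C→A 2.0%), split equally
#' within each pair.
#'
#' @return Named numeric vector of 12 directed weights summing to 1.
#' @export
taq_spectrum <- function() {
  pair_spectrum(c("A>G/T>C" = 66, "G>A/C>T" = 19, "A>T/T>A" = 9.3,
                  "A>C/T>G" = 2.0, "G>C/C>G" = 1.6, "G>T/C>A" = 2.0))
}

#' Cytosine-deamination damage spectrum
#'
#' Thermocycling damage is dominated by C→T changes (deaminated cytosine read
#' as uracil); the default puts `ct_share` of the weight on C→T and spreads
#' the remainder evenly over the other 11 directed changes.
#'
#' @param ct_share Weight on C→T (default 0.97).
#' @return Named numeric vector of 12 directed weights summing to 1.
#' @export
deamination_spectrum <- function(ct_share = 0.97) {
  stopifnot(ct_share >= 0, ct_share <= 1)
  w <- stats::setNames(rep((1 - ct_share) / 11, 12L), SUB_TYPES)
  w["C>T"] <- ct_share
  w
}

check_spectrum <- function(w, what) {
  errs <- character(0)
  if (length(w) != 12L || is.null(names(w)) || !setequal(names(w), SUB_TYPES))
    return(paste0(what, ": must be 12 named directed weights (A>C ... T>G)"))
  if (any(w < 0)) errs <- c(errs, paste0(what, ": weights must be >= 0"))
  if (abs(sum(w) - 1) > 1e-9)
    errs <- c(errs, paste0(what, ": weights must sum to 1 (within 1e-9)"))
  errs
}

#' Simulation configuration
#'
#' Parameters of the PCR process to emulate. Per-doubling rates are
#' probabilities per base per template doubling; the damage rate is per base
#' per thermal cycle. Exactly one of `target_doublings` (closed-form mode)
#' or `efficiency_per_cycle` (lineage-explicit mode) must be given.
#'
#' @param seed Integer master seed (mandatory; all draws derive from it).
#' @param n_reads Number of strand-specific consensus reads to emit.
#' @param sub_rate_per_doubling,del_rate_per_doubling,ins_rate_per_doubling
#'   Polymerase error rates per base per doubling.
#' @param sub_spectrum Directed 12-weight substitution spectrum (sums to 1).
#' @param damage_rate_per_cycle Per-base, per-cycle damage probability.
#' @param damage_spectrum Directed 12-weight damage spectrum.
#' @param n_cycles Number of thermal cycles (drives damage accumulation; in
#'   lineage mode also the number of replication rounds).
#' @param target_doublings Effective doublings `n` (closed-form mode); the
#'   expected raw error fraction is `f = n * e / 2`.
#' @param efficiency_per_cycle Per-cycle replication probability in (0, 1]
#'   (lineage mode).
#' @param initial_molecules Starting molecule count (lineage mode).
#' @param recomb_rate_per_doubling Template-switch rate per base per doubling
#'   between co-amplified homologs.
#' @param inversion_probs Named numeric vector with probabilities for read
#'   classes `single-top`, `single-bottom`, `double` at an annotated
#'   inverted-repeat element (remainder is the correct product).
#' @param read_pass_model Integer vector `c(min_passes, max_passes)`;
#'   consensus pass counts are drawn uniformly in this range.
#' @return A validated object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_reads = 1000L,
                              sub_rate_per_doubling = 0,
                              sub_spectrum = uniform_spectrum(),
                              del_rate_per_doubling = 0,
                              ins_rate_per_doubling = 0,
                              damage_rate_per_cycle = 0,
                              damage_spectrum = deamination_spectrum(),
                              n_cycles = NULL,
                              target_doublings = NULL,
                              efficiency_per_cycle = NULL,
                              initial_molecules = NULL,
                              recomb_rate_per_doubling = 0,
                              inversion_probs = NULL,
                              read_pass_model = c(15L, 40L)) {
  cfg <- list(seed = seed, n_reads = as.integer(n_reads),
              sub_rate_per_doubling = sub_rate_per_doubling,
              sub_spectrum = sub_spectrum[SUB_TYPES],
              del_rate_per_doubling = del_rate_per_doubling,
              ins_rate_per_doubling = ins_rate_per_doubling,
              damage_rate_per_cycle = damage_rate_per_cycle,
              damage_spectrum = damage_spectrum[SUB_TYPES],
              n_cycles = if (!is.null(n_cycles)) as.integer(n_cycles),
              target_doublings = target_doublings,
              efficiency_per_cycle = efficiency_per_cycle,
              initial_molecules =
                if (!is.null(initial_molecules)) as.integer(initial_molecules),
              recomb_rate_per_doubling = recomb_rate_per_doubling,
              inversion_probs = inversion_probs,
              read_pass_model = as.integer(read_pass_model))
  errs <- validate_simulation_config(cfg)
  if (length(errs)) stop(paste(errs, collapse = "\n  "))
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L,
      "seed: an integer seed is mandatory for reproducibility")
  chk(is.numeric(cfg$n_reads) && cfg$n_reads >= 0, "n_reads: must be >= 0")
  for (r in c("sub_rate_per_doubling", "del_rate_per_doubling",
              "ins_rate_per_doubling", "damage_rate_per_cycle",
              "recomb_rate_per_doubling"))
    chk(is.numeric(cfg[[r]]) && cfg[[r]] >= 0 && cfg[[r]] <= 1,
        paste0(r, ": must be a probability in [0,1]"))
  errs <- c(errs, check_spectrum(cfg$sub_spectrum, "sub_spectrum"),
            check_spectrum(cfg$damage_spectrum, "damage_spectrum"))
  has_n <- !is.null(cfg$target_doublings)
  has_eff <- !is.null(cfg$efficiency_per_cycle)
  if (has_n && has_eff)
    errs <- c(errs, paste0("target_doublings/efficiency_per_cycle: exactly ",
                           "one must be given, not both"))
  if (!has_n && !has_eff)
    errs <- c(errs,
              "target_doublings or efficiency_per_cycle: one must be given")
  if (has_n)
    chk(cfg$target_doublings >= 0, "target_doublings: must be >= 0")
  if (has_eff) {
    chk(cfg$efficiency_per_cycle > 0 && cfg$efficiency_per_cycle <= 1,
        "efficiency_per_cycle: must be in (0,1]")
    chk(!is.null(cfg$n_cycles) && cfg$n_cycles >= 1,
        "n_cycles: required in lineage mode")
    chk(!is.null(cfg$initial_molecules) && cfg$initial_molecules >= 1,
        "initial_molecules: required in lineage mode")
  }
  if (cfg$damage_rate_per_cycle > 0)
    chk(!is.null(cfg$n_cycles) && cfg$n_cycles >= 1,
        "n_cycles: required when damage_rate_per_cycle > 0")
  if (!is.null(cfg$inversion_probs)) {
    ip <- cfg$inversion_probs
    ok <- is.numeric(ip) && !is.null(names(ip)) &&
      all(names(ip) %in% c("single-top", "single-bottom", "double")) &&
      all(ip >= 0) && sum(ip) <= 1
    chk(ok, paste0("inversion_probs: named probabilities for single-top/",
                   "single-bottom/double summing to <= 1"))
  }
  chk(length(cfg$read_pass_model) == 2L &&
        cfg$read_pass_model[1L] >= 1L &&
        cfg$read_pass_model[2L] >= cfg$read_pass_model[1L],
      "read_pass_model: must be c(min_passes, max_passes) with min >= 1")
  errs
}
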