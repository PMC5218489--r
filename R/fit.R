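# The top-level estimator: filter -> classify -> mask -> count -> rates,
# returning a classed fit object in the style of R modelling functions.

#' Estimate PCR error rates from consensus reads
#'
#' Runs the full error-rate analysis: read filtering, event classification,
#' event-level quality filtering, primer masking, composition-aware
#' counting, raw and per-doubling-normalized rates, and the mutational
#' spectrum.
#'
#' @param reads Read table ([simulate_amplification()] or
#'   [read_consensus_sam()]).
#' @param templates A [template_set()].
#' @param policy A [filter_policy()]; the `"rates"` preset by default.
#' @param yield,input Measured product yield and input amount (same units);
#'   used to derive doublings `n = log2(yield/input)`. Alternatively give
#'   `doublings` directly.
#' @param doublings Number of doubling events `n` (overrides yield/input).
#' @param cycles Optional number of thermal cycles, enabling the per-cycle
#'   rate `f/cycles`.
#' @param mode Substitution-rate mode: `"composition-averaged"` for
#'   amplicons, `"plain"` for plasmid samples.
#' @param mask_markers When the template set carries a marker table
#'   (co-amplified homologs), marker positions reflect template identity --
#'   a recombinant read mismatches its template of origin there -- so they
#'   are masked from error counting (numerator and denominator) by
#'   default.
#' @return An object of class `pcr_rates` with components `counts`
#'   ([error_counts()]), `rates` (raw and normalized rates: `e_sub_AT`,
#'   `e_sub_GC`, `e_sub`, `e_del`, `e_ins`, `f`, `n`, `e_normalized`,
#'   `per_cycle`, `accuracy`), `spectrum` ([mutational_spectrum()] or NULL
#'   when no substitutions survive), `audit`, `n_events`.
#' @seealso [coef.pcr_rates()], [print.pcr_rates()]
#' @export
estimate_error_rates <- function(reads, templates,
                                 policy = filter_policy("rates"),
                                 yield = NULL, input = NULL,
                                 doublings = NULL, cycles = NULL,
                                 mode = c("composition-averaged", "plain"),
                                 mask_markers = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(templates, "template_set"))
  n <- if (!is.null(doublings)) doublings
       else if (!is.null(yield) && !is.null(input))
         doublings_from_yield(yield, input)
       else NA_real_
  aligned <- reads[reads$aligned %in% TRUE, , drop = FALSE]
  fr <- filter_reads(aligned, templates, policy)
  ev <- classify_errors(fr$reads, templates)
  keep <- check_event_quality(ev$qv, policy)
  masked <- 0L
  maskiv <- NULL
  if (isTRUE(policy$exclude_primer_regions) &&
      !is.null(templates$primer_regions))
    maskiv <- templates$primer_regions
  if (isTRUE(mask_markers) && !is.null(templates$markers))
    maskiv <- rbind(maskiv,
                    data.frame(start = templates$markers$position,
                               end = templates$markers$position))
  if (!is.null(maskiv)) {
    inmask <- in_regions(ev$pos, maskiv)
    masked <- sum(inmask & keep)
    keep <- keep & !inmask
  }
  ev <- ev[keep, , drop = FALSE]
  counts <- tally_error_counts(ev, fr$reads, templates, mask = maskiv)
  sr <- tryCatch(substitution_rate(counts, mode), error = function(e) NULL)
  ir <- tryCatch(indel_rates(counts), error = function(e) NULL)
  f <- if (mode == "plain") sr else sr$e
  rates <- list(
    e_sub_AT = if (mode == "plain") NA_real_ else sr$e_AT,
    e_sub_GC = if (mode == "plain") NA_real_ else sr$e_GC,
    e_sub = f,
    e_del = ir$e_del, e_ins = ir$e_ins,
    f = f, n = n,
    e_normalized = if (!is.na(n) && n > 0 && !is.null(f))
      normalize_per_doubling(f, n) else NA_real_,
    e_del_normalized = if (!is.na(n) && n > 0 && !is.null(ir))
      normalize_per_doubling(ir$e_del, n) else NA_real_,
    e_ins_normalized = if (!is.na(n) && n > 0 && !is.null(ir))
      normalize_per_doubling(ir$e_ins, n) else NA_real_,
    per_cycle = if (!is.null(cycles) && !is.null(f))
      per_cycle_rate(f, cycles) else NA_real_,
    accuracy = if (!is.null(f) && f > 0) 1 / f else NA_real_)
  spec <- if (sum(counts$subs) > 0) mutational_spectrum(counts) else NULL
  structure(list(counts = counts, rates = rates, spectrum = spec,
                 audit = fr$audit, n_events = nrow(ev),
                 masked_events = masked, mode = mode,
                 call = match.call()),
            class = "pcr_rates")
}

#' @method coef pcr_rates
#' @export
coef.pcr_rates <- function(object, ...) {
  r <- object$rates
  c(substitution = r$e_sub, deletion = r$e_del, insertion = r$e_ins,
    substitution_per_doubling = r$e_normalized,
    deletion_per_doubling = r$e_del_normalized,
    insertion_per_doubling = r$e_ins_normalized)
}

fmt_rate <- function(x) {
  ifelse(is.na(x), "-",
         ifelse(x == 0, "0", sprintf("%.1e", signif(x, 2))))
}

#' @export
print.pcr_rates <- function(x, ...) {
  r <- x$rates
  cat("PCR error-rate fit (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  analyzed bases: %s (A %s, C %s, G %s, T %s)\n",
              format(x$counts$N, big.mark = ","),
              format(x$counts$N_A, big.mark = ","),
              format(x$counts$N_C, big.mark = ","),
              format(x$counts$N_G, big.mark = ","),
              format(x$counts$N_T, big.mark = ",")))
  cat(sprintf("  events: %d substitutions, %d deletions, %d insertions\n",
              sum(x$counts$subs), x$counts$N_deletion,
              x$counts$N_insertion))
  cat(sprintf("  raw rates: sub %s, del %s, ins %s (per base)\n",
              fmt_rate(r$e_sub), fmt_rate(r$e_del), fmt_rate(r$e_ins)))
  if (!is.na(r$n))
    cat(sprintf("  per doubling (n = %.2f): sub %s, del %s, ins %s\n",
                r$n, fmt_rate(r$e_normalized),
                fmt_rate(r$e_del_normalized), fmt_rate(r$e_ins_normalized)))
  if (!is.na(r$per_cycle))
    cat(sprintf("  per cycle: %s\n", fmt_rate(r$per_cycle)))
  if (!is.na(r$accuracy))
    cat(sprintf("  accuracy: 1 error per %s bases\n",
                format(round(r$accuracy), big.mark = ",")))
  invisible(x)
}

#' @method summary pcr_rates
#' @export
summary.pcr_rates <- function(object, ...) {
  print(object)
  print(object$audit)
  if (!is.null(object$spectrum)) print(object$spectrum)
  invisible(object)
}
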