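# PCR-mediated recombination between co-amplified marker-bearing homologs:
# marker calling (with flanking-base confirmation), switch counting across
# valid calls, cryptic doubling (a switch between identical templates is
# invisible in a 50:50 mix, so detected events are doubled), and Eq-6-style
# per-doubling normalization of the raw rate.

#' Call marker identities along an aligned read
#'
#' For each marker, the read base at the marker position is called `A` or
#' `B` when it matches that homolog's allele AND the two bases on either
#' side match the shared reference backbone; otherwise the call is
#' `invalid` (including markers lost to deletions or outside the
#' alignment).
#'
#' @param read A single-row read table entry (or list with `sequence`,
#'   `pos`, `cigar`).
#' @param markers A [marker_table()].
#' @param reference The backbone reference sequence the read is aligned to
#'   (homolog A; flanking bases are shared between homologs).
#' @return Character vector of calls (`"A"`, `"B"`, `"invalid"`), one per
#'   marker.
#' @export
call_markers <- function(read, markers, reference) {
  if (any(markers$position > nchar(reference)))
    stop("marker position outside the reference")
  call_marker_matrix(as.data.frame(read, stringsAsFactors = FALSE),
                     markers, reference)[1L, ]
}

#' Call markers for a whole read table
#'
#' Vectorized form of [call_markers()]: returns a reads x markers character
#' matrix of calls.
#'
#' @inheritParams call_markers
#' @param reads Read table.
#' @return Character matrix (`nrow(reads)` x `nrow(markers)`) of
#'   `"A"`/`"B"`/`"invalid"` calls.
#' @export
call_marker_matrix <- function(reads, markers, reference) {
  if (any(markers$position > nchar(reference)))
    stop("marker position outside the reference")
  n <- nrow(reads)
  m <- nrow(markers)
  out <- matrix("invalid", n, m)
  if (!n) return(out)
  simple <- grepl("^\\d+M$", reads$cigar) & reads$pos == 1L
  Ls <- nchar(reads$sequence)
  for (k in seq_len(m)) {
    p <- markers$position[k]
    lf <- substr(reference, p - 2L, p - 1L)
    rf <- substr(reference, p + 1L, p + 2L)
    idx <- which(simple & Ls >= p + 2L & p > 2L)
    if (length(idx)) {
      w <- substr(reads$sequence[idx], p - 2L, p + 2L)
      ctr <- substr(w, 3L, 3L)
      ok <- substr(w, 1L, 2L) == lf & substr(w, 4L, 5L) == rf
      call <- ifelse(!ok, "invalid",
                     ifelse(ctr == markers$allele_a[k], "A",
                            ifelse(ctr == markers$allele_b[k], "B",
                                   "invalid")))
      out[idx, k] <- call
    }
  }
  hard <- which(!simple)
  for (i in hard) {
    map <- ref_to_read_map(reads$cigar[i], reads$pos[i],
                           nchar(reference))
    for (k in seq_len(m)) {
      p <- markers$position[k]
      if (p <= 2L || p + 2L > length(map)) next
      w <- map[(p - 2L):(p + 2L)]
      if (anyNA(w)) next
      bases <- substring(reads$sequence[i], w, w)
      ref5 <- substring(reference, (p - 2L):(p + 2L), (p - 2L):(p + 2L))
      if (!all(bases[-3L] == ref5[-3L])) next
      out[i, k] <- if (bases[3L] == markers$allele_a[k]) "A"
                   else if (bases[3L] == markers$allele_b[k]) "B"
                   else "invalid"
    }
  }
  out
}

# read index for each reference position (NA where deleted / uncovered)
ref_to_read_map <- function(cigar, start, ref_len) {
  map <- rep(NA_integer_, ref_len)
  p <- parse_cigar(cigar)
  rp <- start; qp <- 1L
  for (k in seq_along(p$op)) {
    len <- p$len[k]
    op <- p$op[k]
    if (op %in% c("M", "=", "X")) {
      map[rp:(rp + len - 1L)] <- qp:(qp + len - 1L)
      rp <- rp + len; qp <- qp + len
    } else if (op %in% c("D", "N")) rp <- rp + len
    else if (op %in% c("I", "S")) qp <- qp + len
  }
  map
}

#' Count template switches in a marker-call vector
#'
#' A switch is a transition between consecutive VALID calls that differ;
#' invalid calls are skipped (a transition is still counted across them).
#' Fewer than two valid calls yield zero.
#'
#' @param calls Character vector of `"A"`/`"B"`/`"invalid"` calls.
#' @return Integer switch count.
#' @export
count_switches <- function(calls) {
  v <- calls[calls != "invalid"]
  if (length(v) < 2L) return(0L)
  sum(v[-1L] != v[-length(v)])
}

#' Recombination rate with cryptic doubling and per-doubling normalization
#'
#' Recombination between identical co-amplified templates is invisible to
#' marker-based detection, so in an equimolar two-template mix the detected
#' event count is doubled: `raw = 2*events/total_bases`. The raw rate is
#' then normalized for propagation through PCR: `normalized = raw*2/n`.
#'
#' @param events Detected switch events (N_re).
#' @param total_bases Total analyzed consensus bases (N_total).
#' @param n Doubling events.
#' @return List with `N_re`, `N_total`, `raw_rate`, `n`, `normalized_rate`.
#' @export
recombination_rate <- function(events, total_bases, n) {
  if (!(total_bases > 0)) stop("undefined rate: no analyzed bases")
  raw <- 2 * events / total_bases
  list(N_re = events, N_total = total_bases, raw_rate = raw, n = n,
       normalized_rate = if (!is.null(n) && !is.na(n))
         normalize_per_doubling(raw, n) else NA_real_)
}

#' Percentage of strands with at least one detected recombination event
#'
#' @param switch_counts Integer vector of per-read switch counts.
#' @return Percentage in \[0, 100\].
#' @export
fraction_with_event <- function(switch_counts) {
  if (!length(switch_counts)) stop("no marker vectors supplied")
  100 * mean(switch_counts >= 1L)
}

#' Distribution of switch events over adjacent-marker intervals
#'
#' Each detected switch is attributed to the interval between the flanking
#' valid markers, keyed by the left marker's index (a switch bridging
#' invalid calls is attributed to the interval starting at the last valid
#' marker before it).
#'
#' @param call_matrix Character matrix of calls from
#'   [call_marker_matrix()].
#' @return Integer vector of length `ncol(call_matrix) - 1`; entry `i`
#'   counts switches first visible after valid marker `i`. Sums to the
#'   total number of detected events.
#' @export
per_interval_distribution <- function(call_matrix) {
  m <- ncol(call_matrix)
  counts <- stats::setNames(integer(m - 1L),
                            paste0("interval_", seq_len(m - 1L)))
  for (i in seq_len(nrow(call_matrix))) {
    v <- call_matrix[i, ]
    valid <- which(v != "invalid")
    if (length(valid) < 2L) next
    r <- v[valid]
    tr <- which(r[-1L] != r[-length(r)])
    if (length(tr)) {
      left <- valid[tr]
      counts[left] <- counts[left] + 1L
    }
  }
  counts
}

#' Scan reads for PCR-mediated recombination
#'
#' Calls markers on every read passing the pass-count requirement, counts
#' switches, and assembles the full recombination result: detected events,
#' doubled raw rate, per-doubling normalized rate, fraction of strands with
#' at least one event, and the per-interval distribution.
#'
#' @param reads Read table aligned to the homolog-A coordinate frame.
#' @param templates A [template_set()] with a homolog pair and marker
#'   table.
#' @param doublings Doubling events `n` used for normalization (or give
#'   `yield` and `input`).
#' @param yield,input Product yield and input amount, from which
#'   `n = log2(yield/input)`.
#' @param min_passes Minimum consensus passes (default 3).
#' @return An object of class `recomb_scan` with fields `N_re`, `N_total`,
#'   `raw_rate`, `n`, `normalized_rate`, `strands_with_event_pct`,
#'   `per_interval`, `n_reads`, `switch_counts`.
#' @export
scan_recombination <- function(reads, templates, doublings = NULL,
                               yield = NULL, input = NULL,
                               min_passes = 3L) {
  stopifnot(inherits(templates, "template_set"))
  if (is.null(templates$markers))
    stop("template set carries no marker table")
  n <- if (!is.null(doublings)) doublings
       else if (!is.null(yield) && !is.null(input))
         doublings_from_yield(yield, input)
       else NA_real_
  ha <- names(templates$roles)[templates$roles == "homolog-A"]
  reads <- reads[reads$aligned %in% TRUE & reads$n_passes >= min_passes, ,
                 drop = FALSE]
  cm <- call_marker_matrix(reads, templates$markers,
                           templates$sequences[[ha]])
  sw <- apply(cm, 1L, count_switches)
  if (!nrow(reads)) sw <- integer(0)
  total_bases <- sum(nchar(reads$sequence))
  rr <- recombination_rate(sum(sw), total_bases, n)
  structure(c(rr,
              list(strands_with_event_pct = fraction_with_event(sw),
                   per_interval = per_interval_distribution(cm),
                   n_reads = nrow(reads), switch_counts = sw)),
            class = "recomb_scan")
}

#' @export
print.recomb_scan <- function(x, ...) {
  cat("PCR-mediated recombination scan\n")
  cat(sprintf("  N_re = %s events over N_total = %s bases (%d strands)\n",
              format(x$N_re, big.mark = ","),
              format(x$N_total, big.mark = ","), x$n_reads))
  cat(sprintf("  raw rate (doubled for cryptic events): %s per base\n",
              fmt_rate(x$raw_rate)))
  if (!is.na(x$n))
    cat(sprintf("  normalized (n = %.2f doublings): %s per base/doubling\n",
                x$n, fmt_rate(x$normalized_rate)))
  cat(sprintf("  strands with >= 1 event: %s%%\n",
              fmt_pct(x$strands_with_event_pct)))
  invisible(x)
}
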