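# Error-event classification and rate estimation.
#
# Raw substitution rates are composition-averaged: with N^A..N^C the totals
# of analyzed A/T/G/C consensus bases,
#   e_AT = (subs from A + subs from T) / (N^A + N^T)
#   e_GC = (subs from G + subs from C) / (N^G + N^C)
#   e_sub = (e_AT + e_GC) / 2
# (plain mode divides total substitutions by total bases, as for plasmid
# samples). Indel rates are N_del/N and N_ins/N. Raw fractions f are
# normalized for propagation through exponential amplification by
# e_normalized = f * 2 / n with n = log2(yield/input) doubling events,
# the inverse of the first-order propagation model f = n * e / 2.

parse_cigar <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar, perl = TRUE)[[1L]]
  if (m[1L] == -1L) stop("unparseable CIGAR: ", cigar)
  tok <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", tok)),
       op = sub("^\\d+", "", tok))
}

cigar_ref_span <- function(cigar, seq_len_hint = NULL) {
  vapply(seq_along(cigar), function(i) {
    cg <- cigar[i]
    if (grepl("^\\d+M$", cg)) return(as.integer(sub("M$", "", cg)))
    p <- parse_cigar(cg)
    sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1L))
}

#' Classify error events from aligned consensus reads
#'
#' Walks each read's alignment against its reference and emits one event per
#' mismatched base (substitution), per deleted reference base, and per
#' inserted read base. Positions are reference coordinates (1-based).
#' The `change` column gives the directed base change in the orientation of
#' the sequenced strand (complemented for minus-strand reads), which is the
#' orientation spectra are tallied in; `ref_base`/`read_base` stay in
#' reference orientation. A deletion's quality value is the minimum of the
#' two flanking read bases.
#'
#' @param reads Read table (aligned reads only).
#' @param templates A [template_set()] containing every reference named in
#'   `reads$ref`.
#' @return A data.frame with columns `read_id`, `ref`, `strand`, `pos`,
#'   `kind` (`sub`/`del`/`ins`), `ref_base`, `read_base`, `qv`, `change`.
#' @export
classify_errors <- function(reads, templates) {
  stopifnot(inherits(templates, "template_set"))
  unknown <- setdiff(unique(reads$ref), names(templates$sequences))
  if (length(unknown))
    stop("alignment references unknown sequence(s): ",
         paste(unknown, collapse = ", "))
  seqs <- templates$sequences
  refraw <- lapply(seqs, charToRaw)
  acc <- list(); ai <- 0L
  add <- function(df) { ai <<- ai + 1L; acc[[ai]] <<- df }
  n <- nrow(reads)
  if (n) for (i in seq_len(n)) {
    if (isFALSE(reads$aligned[i])) next
    seq <- reads$sequence[i]
    cg <- reads$cigar[i]
    start <- reads$pos[i]
    rid <- reads$read_id[i]
    rf <- reads$ref[i]
    qv <- utf8ToInt(reads$qual[i]) - 33L
    rraw <- charToRaw(seq)
    tr <- refraw[[rf]]
    simple <- grepl("^\\d+M$", cg)
    if (simple) {
      len <- length(rraw)
      mm <- which(rraw != tr[start:(start + len - 1L)])
      if (length(mm))
        add(data.frame(
          read_id = rid, ref = rf, strand = reads$strand[i],
          pos = start + mm - 1L, kind = "sub",
          ref_base = rawToChar(tr[start + mm - 1L], multiple = TRUE),
          read_base = rawToChar(rraw[mm], multiple = TRUE),
          qv = qv[mm], stringsAsFactors = FALSE))
      next
    }
    p <- parse_cigar(cg)
    rp <- start; qp <- 1L
    for (k in seq_along(p$op)) {
      len <- p$len[k]
      op <- p$op[k]
      if (op %in% c("M", "=", "X")) {
        mm <- which(rraw[qp:(qp + len - 1L)] != tr[rp:(rp + len - 1L)])
        if (length(mm))
          add(data.frame(
            read_id = rid, ref = rf, strand = reads$strand[i],
            pos = rp + mm - 1L, kind = "sub",
            ref_base = rawToChar(tr[rp + mm - 1L], multiple = TRUE),
            read_base = rawToChar(rraw[qp + mm - 1L], multiple = TRUE),
            qv = qv[qp + mm - 1L], stringsAsFactors = FALSE))
        rp <- rp + len; qp <- qp + len
      } else if (op == "D") {
        flank <- c(max(qp - 1L, 1L), min(qp, length(qv)))
        add(data.frame(
          read_id = rid, ref = rf, strand = reads$strand[i],
          pos = rp:(rp + len - 1L), kind = "del",
          ref_base = rawToChar(tr[rp:(rp + len - 1L)], multiple = TRUE),
          read_base = "-", qv = min(qv[flank]), stringsAsFactors = FALSE))
        rp <- rp + len
      } else if (op == "I") {
        add(data.frame(
          read_id = rid, ref = rf, strand = reads$strand[i],
          pos = rp - 1L, kind = "ins", ref_base = "-",
          read_base = rawToChar(rraw[qp:(qp + len - 1L)], multiple = TRUE),
          qv = qv[qp:(qp + len - 1L)], stringsAsFactors = FALSE))
        qp <- qp + len
      } else if (op %in% c("S", "N")) {
        if (op == "S") qp <- qp + len else rp <- rp + len
      }
    }
  }
  acc <- acc[seq_len(ai)]
  ev <- if (ai) do.call(rbind, acc) else
    data.frame(read_id = character(0), ref = character(0),
               strand = character(0), pos = integer(0), kind = character(0),
               ref_base = character(0), read_base = character(0),
               qv = integer(0), stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  ev$change <- rep(NA_character_, nrow(ev))
  if (nrow(ev)) {
    is_sub <- ev$kind == "sub"
    chg <- paste0(ev$ref_base[is_sub], ">", ev$read_base[is_sub])
    minus <- ev$strand[is_sub] == "-"
    chg[minus] <- complement_type(chg[minus])
    ev$change[is_sub] <- chg
  }
  ev
}

in_regions <- function(pos, regions) {
  if (is.null(regions) || !nrow(regions)) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (r in seq_len(nrow(regions)))
    hit <- hit | (pos >= regions$start[r] & pos <= regions$end[r])
  hit
}

#' Error-count container
#'
#' Totals of analyzed consensus bases by identity, the 12 directed
#' substitution counts (in sequenced-strand orientation), and indel counts.
#'
#' @param N_A,N_C,N_G,N_T Analyzed base totals.
#' @param subs Named integer vector over the 12 directed changes
#'   (`A>C` ... `T>G`).
#' @param N_deletion,N_insertion Event totals.
#' @return An object of class `error_counts` with derived total `N`.
#' @export
error_counts <- function(N_A = 0, N_C = 0, N_G = 0, N_T = 0,
                         subs = stats::setNames(integer(12L), SUB_TYPES),
                         N_deletion = 0, N_insertion = 0) {
  subs <- subs[SUB_TYPES]
  subs[is.na(subs)] <- 0L
  storage.mode(subs) <- "integer"
  names(subs) <- SUB_TYPES
  x <- list(N_A = N_A, N_C = N_C, N_G = N_G, N_T = N_T,
            N = N_A + N_C + N_G + N_T, subs = subs,
            N_deletion = N_deletion, N_insertion = N_insertion)
  if (any(unlist(x[c("N_A", "N_C", "N_G", "N_T")]) < 0) || any(subs < 0) ||
      N_deletion < 0 || N_insertion < 0)
    stop("counts must be non-negative")
  for (b in DNA_BASES) {
    from_b <- sum(subs[substr(SUB_TYPES, 1L, 1L) == b])
    if (from_b > x[[paste0("N_", b)]])
      stop("substitutions from ", b, " exceed the analyzed total of ", b)
  }
  structure(x, class = "error_counts")
}

# interval base composition of a reference, via cumulative counts
composition_fn <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  cums <- sapply(DNA_BASES, function(b) cumsum(v == b))
  function(start, end) {
    if (end < start) return(stats::setNames(numeric(4L), DNA_BASES))
    hi <- cums[end, ]
    lo <- if (start > 1L) cums[start - 1L, ] else stats::setNames(
      numeric(4L), DNA_BASES)
    hi - lo
  }
}

#' Tally error counts from classified events and surviving reads
#'
#' Computes the analyzed-base denominators (reference span of each surviving
#' read, minus masked primer positions, complemented into read orientation
#' for minus-strand reads, adjusted for the read's own indels) and the 12
#' directed substitution counts from the events. Events must already have
#' passed event-level filters; masked events must already be excluded.
#'
#' @param events Event table from [classify_errors()] (post filtering).
#' @param reads The surviving read table the events came from.
#' @param templates The [template_set()].
#' @param mask Optional data.frame of `start`,`end` intervals excluded from
#'   the denominators (primer regions).
#' @return An [error_counts()] object.
#' @export
tally_error_counts <- function(events, reads, templates, mask = NULL) {
  seqs <- templates$sequences
  comp_fns <- lapply(seqs, composition_fn)
  span <- ifelse(grepl("^\\d+M$", reads$cigar),
                 nchar(reads$sequence),
                 cigar_ref_span(reads$cigar))
  key <- paste(reads$ref, reads$pos, span, reads$strand)
  uk <- !duplicated(key)
  comp_by_key <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    cf <- comp_fns[[reads$ref[i]]]
    a <- reads$pos[i]; b <- reads$pos[i] + span[i] - 1L
    cc <- cf(a, b)
    if (!is.null(mask) && nrow(mask)) {
      for (r in seq_len(nrow(mask))) {
        lo <- max(a, mask$start[r]); hi <- min(b, mask$end[r])
        if (lo <= hi) cc <- cc - cf(lo, hi)
      }
    }
    if (reads$strand[i] == "-")
      cc <- cc[c("T", "G", "C", "A")]   # complement into read orientation
    names(cc) <- DNA_BASES
    assign(key[i], cc, envir = comp_by_key)
  }
  tot <- stats::setNames(numeric(4L), DNA_BASES)
  kt <- table(key)
  for (k in names(kt)) tot <- tot + get(k, envir = comp_by_key) * kt[[k]]
  # indels change the number of consensus bases actually analyzed
  subs <- stats::setNames(integer(12L), SUB_TYPES)
  ndel <- 0L; nins <- 0L
  if (nrow(events)) {
    is_sub <- events$kind == "sub"
    if (any(is_sub)) {
      tb <- table(factor(events$change[is_sub], levels = SUB_TYPES))
      subs <- stats::setNames(as.integer(tb), SUB_TYPES)
    }
    dels <- events[events$kind == "del", , drop = FALSE]
    inss <- events[events$kind == "ins", , drop = FALSE]
    ndel <- nrow(dels); nins <- nrow(inss)
    if (ndel) {
      b <- ifelse(dels$strand == "-", complement_bases(dels$ref_base),
                  dels$ref_base)
      tb <- table(factor(b, levels = DNA_BASES))
      tot <- tot - as.numeric(tb)
    }
    if (nins) {
      b <- ifelse(inss$strand == "-", complement_bases(inss$read_base),
                  inss$read_base)
      tb <- table(factor(b, levels = DNA_BASES))
      tot <- tot + as.numeric(tb)
    }
  }
  error_counts(N_A = tot[["A"]], N_C = tot[["C"]], N_G = tot[["G"]],
               N_T = tot[["T"]], subs = subs,
               N_deletion = ndel, N_insertion = nins)
}

#' Raw substitution rate from error counts
#'
#' @param counts An [error_counts()] object.
#' @param mode `"composition-averaged"` (the default; average of the A/T and
#'   G/C rates) or `"plain"` (total substitutions over total bases, as used
#'   for plasmid samples).
#' @return For composition-averaged mode, a named list `e_AT`, `e_GC`, `e`;
#'   for plain mode a single rate.
#' @export
substitution_rate <- function(counts,
                              mode = c("composition-averaged", "plain")) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "error_counts"))
  src <- substr(SUB_TYPES, 1L, 1L)
  if (mode == "plain") {
    if (counts$N <= 0) stop("undefined rate: no analyzed bases")
    return(sum(counts$subs) / counts$N)
  }
  nAT <- counts$N_A + counts$N_T
  nGC <- counts$N_G + counts$N_C
  if (nAT <= 0 || nGC <= 0)
    stop("undefined rate: zero A/T or G/C denominator")
  e_AT <- sum(counts$subs[src %in% c("A", "T")]) / nAT
  e_GC <- sum(counts$subs[src %in% c("G", "C")]) / nGC
  list(e_AT = e_AT, e_GC = e_GC, e = (e_AT + e_GC) / 2)
}

#' Deletion and insertion rates
#'
#' @param counts An [error_counts()] object.
#' @return Named list with `e_del = N_deletion/N` and `e_ins = N_insertion/N`.
#' @export
indel_rates <- function(counts) {
  stopifnot(inherits(counts, "error_counts"))
  if (counts$N <= 0) stop("undefined rate: no analyzed bases")
  list(e_del = counts$N_deletion / counts$N,
       e_ins = counts$N_insertion / counts$N)
}

#' Doubling events from product yield
#'
#' The number of effective template doublings during amplification,
#' `n = log2(Y/I)`, from measured product yield `Y` and input amount `I`
#' (same mass units).
#'
#' @param yield Product yield.
#' @param input Input amount.
#' @return Number of doubling events.
#' @export
doublings_from_yield <- function(yield, input) {
  if (!(input > 0)) stop("input amount must be positive")
  if (yield < input) stop("yield below input: no amplification to normalize")
  log2(yield / input)
}

#' Normalize a raw error fraction to a per-doubling rate
#'
#' Inverse of the propagation model `f = n*e/2`: errors introduced early in
#' PCR are propagated through subsequent cycles, so the observed fraction
#' grows linearly with the number of doubling events.
#'
#' @param f Raw per-base error fraction.
#' @param n Number of doubling events (> 0).
#' @return Per-base, per-doubling rate `e = f*2/n`.
#' @export
normalize_per_doubling <- function(f, n) {
  if (!(n > 0)) stop("doubling events n must be positive")
  if (any(f < 0)) stop("raw fraction must be non-negative")
  f * 2 / n
}

#' Per-cycle rate from a raw fraction
#'
#' @param f Raw per-base fraction accumulated over `cycles` thermal cycles.
#' @param cycles Number of cycles (> 0).
#' @return Per-base, per-cycle rate `f/cycles`.
#' @export
per_cycle_rate <- function(f, cycles) {
  if (!(cycles > 0)) stop("cycles must be positive")
  f / cycles
}

#' Mutational spectrum over the six complementary pairs
#'
#' @param x An [error_counts()] object or a named vector of directed
#'   substitution counts (`A>C` ... `T>G`).
#' @return An object of class `spectrum_table`: `pairs` (percentages over
#'   the six complementary pairs, summing to 100), `directed` (percentages
#'   over the 12 directed changes), `total` (event count).
#' @export
mutational_spectrum <- function(x) {
  subs <- if (inherits(x, "error_counts")) x$subs else x[SUB_TYPES]
  subs[is.na(subs)] <- 0
  total <- sum(subs)
  if (total <= 0) stop("undefined spectrum: no substitution events")
  pairs <- vapply(SPECTRUM_PAIRS, function(tp) sum(subs[tp]) / total * 100,
                  numeric(1L))
  structure(list(pairs = pairs, directed = subs / total * 100,
                 total = total),
            class = "spectrum_table")
}

fmt_pct <- function(x) ifelse(x >= 10, sprintf("%.0f", x),
                              sprintf("%.1f", x))

#' @export
print.spectrum_table <- function(x, ...) {
  cat("Mutational spectrum (", x$total, " substitutions):\n", sep = "")
  out <- fmt_pct(x$pairs)
  for (i in seq_along(out))
    cat(sprintf("  %-8s %s%%\n", names(x$pairs)[i], out[i]))
  invisible(x)
}
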