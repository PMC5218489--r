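# Consensus-read and per-event quality filters applied before any rate
# computation. Survivorship is a conjunction of criteria; the audit
# attributes each removed read to the first failing criterion in the order
# passes -> mapq -> length -> chimeric (a reporting choice only).

#' Filtering policy for consensus reads and events
#'
#' Two presets ship: `"rates"` is the strict policy for error-rate
#' estimation (at least 15 passes, every event at the maximum quality value
#' of 93, MAPQ 254, read length at least 80% of the expected amplicon,
#' primer regions masked, chimeric reads dropped); `"switching"` is the
#' permissive policy for inversion and recombination scans (at least 3
#' passes, no further read-level requirements).
#'
#' @param preset `"rates"` or `"switching"`.
#' @param min_passes,require_max_event_qv,require_mapq,min_length_fraction,
#'   exclude_primer_regions,drop_chimeric Override individual fields;
#'   `require_mapq = NULL` disables the MAPQ criterion,
#'   `min_length_fraction = NULL` disables the length criterion.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(preset = c("rates", "switching"),
                          min_passes = NULL,
                          require_max_event_qv = NULL,
                          require_mapq = NULL,
                          min_length_fraction = NULL,
                          exclude_primer_regions = NULL,
                          drop_chimeric = NULL) {
  preset <- match.arg(preset)
  pol <- if (preset == "rates") {
    list(min_passes = 15L, require_max_event_qv = TRUE,
         require_mapq = 254L, min_length_fraction = 0.80,
         exclude_primer_regions = TRUE, drop_chimeric = TRUE)
  } else {
    list(min_passes = 3L, require_max_event_qv = FALSE,
         require_mapq = NULL, min_length_fraction = NULL,
         exclude_primer_regions = FALSE, drop_chimeric = FALSE)
  }
  ovr <- list(min_passes = min_passes,
              require_max_event_qv = require_max_event_qv,
              require_mapq = require_mapq,
              min_length_fraction = min_length_fraction,
              exclude_primer_regions = exclude_primer_regions,
              drop_chimeric = drop_chimeric)
  miss <- c(missing(min_passes), missing(require_max_event_qv),
            missing(require_mapq), missing(min_length_fraction),
            missing(exclude_primer_regions), missing(drop_chimeric))
  for (k in names(ovr)[!miss]) pol[[k]] <- ovr[[k]]
  if (!is.null(pol$min_length_fraction) &&
      (pol$min_length_fraction <= 0 || pol$min_length_fraction > 1))
    stop("min_length_fraction must be in (0, 1]")
  if (pol$min_passes < 0) stop("min_passes must be non-negative")
  structure(c(pol, list(preset = preset)), class = "filter_policy")
}

#' Expected-amplicon specification used by the length filter
#'
#' @param expected_length Expected amplicon length in bases.
#' @param primer_regions Optional data.frame of `start`,`end` primer
#'   intervals (1-based inclusive, reference coordinates).
#' @return A list of class `amplicon_spec`.
#' @export
amplicon_spec <- function(expected_length, primer_regions = NULL) {
  structure(list(expected_length = as.integer(expected_length),
                 primer_regions = primer_regions),
            class = "amplicon_spec")
}

as_amplicon_spec <- function(x) {
  if (inherits(x, "amplicon_spec")) return(x)
  if (inherits(x, "template_set"))
    return(amplicon_spec(max(nchar(x$sequences)), x$primer_regions))
  stop("expected an amplicon_spec or template_set")
}

#' Filter consensus reads
#'
#' Applies the read-level criteria of `policy` and returns the surviving
#' reads with an audit of removals. Every input read is either retained or
#' attributed to exactly one removal category (the first failing criterion
#' in the order passes, mapq, length, chimeric).
#'
#' @param reads Read table (see [simulate_amplification()] /
#'   [read_consensus_sam()]).
#' @param spec An [amplicon_spec()] or [template_set()] (used for the
#'   expected length and primer regions).
#' @param policy A [filter_policy()].
#' @return A list of class `filter_result`: `reads` (surviving),
#'   `audit` (class `filter_audit`: named removal counts, input/surviving
#'   totals, the policy used).
#' @export
filter_reads <- function(reads, spec, policy = filter_policy("rates")) {
  stopifnot(inherits(policy, "filter_policy"))
  spec <- as_amplicon_spec(spec)
  need <- c("read_id", "n_passes", "mapq", "sequence")
  miss <- setdiff(need, names(reads))
  if (length(miss))
    stop("malformed read table: missing column(s) ",
         paste(miss, collapse = ", "))
  bad <- which(is.na(reads$n_passes) | is.na(reads$mapq))
  if (length(bad))
    stop("read(s) lacking pass count or MAPQ: ",
         paste(utils::head(reads$read_id[bad], 3L), collapse = ", "))
  n <- nrow(reads)
  fail <- rep(NA_character_, n)
  mark <- function(cond, label) {
    fail[is.na(fail) & cond] <<- label
  }
  mark(reads$n_passes < policy$min_passes, "passes")
  if (!is.null(policy$require_mapq))
    mark(reads$mapq < policy$require_mapq, "mapq")
  if (!is.null(policy$min_length_fraction))
    mark(nchar(reads$sequence) <
           policy$min_length_fraction * spec$expected_length, "length")
  if (isTRUE(policy$drop_chimeric)) {
    if ("chimeric" %in% names(reads)) {
      mark(reads$chimeric %in% TRUE, "chimeric")
    } else {
      # a read id occurring with more than one reference is chimeric
      nref <- tapply(reads$ref, reads$read_id,
                     function(x) length(unique(x)))
      mark(nref[reads$read_id] > 1L, "chimeric")
    }
  }
  cats <- c("passes", "mapq", "length", "chimeric")
  removed <- stats::setNames(vapply(cats, function(k) sum(fail %in% k),
                                    integer(1L)), cats)
  out <- reads[is.na(fail), , drop = FALSE]
  rownames(out) <- NULL
  audit <- structure(list(input = n, surviving = nrow(out),
                          removed = removed, policy = policy),
                     class = "filter_audit")
  structure(list(reads = out, audit = audit), class = "filter_result")
}

#' @export
print.filter_audit <- function(x, ...) {
  cat(sprintf("Read filter (%s policy): %d in, %d surviving\n",
              x$policy$preset, x$input, x$surviving))
  for (k in names(x$removed))
    if (x$removed[[k]] > 0)
      cat(sprintf("  removed (%s): %d\n", k, x$removed[[k]]))
  invisible(x)
}

#' Event-level quality check
#'
#' An individual substitution, deletion or insertion is kept only if its
#' quality value is the maximum possible (93) when the policy demands it.
#'
#' @param qv Integer vector of event quality values (0-93).
#' @param policy A [filter_policy()].
#' @return Logical vector: keep (`TRUE`) or drop (`FALSE`).
#' @export
check_event_quality <- function(qv, policy = filter_policy("rates")) {
  if (!isTRUE(policy$require_max_event_qv)) return(rep(TRUE, length(qv)))
  !is.na(qv) & qv == 93L
}
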