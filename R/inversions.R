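# Template-switching (inversion) detection: each read is classified against
# four constructed references — the correct local sequence and the three
# switch products — requiring > 95% coverage of the matched reference with
# zero mismatches. An exact full-reference substring match satisfies the
# rule directly; reads without one fall back to alignment
# (Biostrings::pairwiseAlignment) where the zero-mismatch/zero-indel,
# coverage > 0.95 criteria are enforced. Ambiguous reads (matching more
# than one reference) are unassigned.

INVERSION_CLASSES <- c("correct", "single-top", "single-bottom", "double")

#' Build the four classification references for an inverted-repeat element
#'
#' Each reference covers the element (both stems and the loop) plus `flank`
#' adjacent nucleotides on each available side: the faithful sequence
#' (`correct`), the loop reverse-complemented in place (`double`), and the
#' two truncated single-switch fold-back products (`single-top`,
#' `single-bottom`).
#'
#' @param template Template sequence (character string).
#' @param element An [inverted_repeat_element()].
#' @param flank Flanking context in bases (default 30).
#' @return An object of class `inversion_quad`: `element`, `flank`, and
#'   `refs`, a named character vector with the four references.
#' @export
build_inversion_references <- function(template, element, flank = 30L) {
  stopifnot(inherits(element, "inverted_repeat"))
  L <- nchar(template)
  s <- element$start; e <- element$end
  k <- element$stem_length; l <- element$loop_length
  if (s < 1L || e > L) stop("element lies outside the template")
  a <- max(1L, s - flank)
  b <- min(L, e + flank)
  ls <- s + k; le <- s + k + l - 1L
  refs <- c(
    "correct" = substr(template, a, b),
    "double" = paste0(substr(template, a, ls - 1L),
                      revcomp(substr(template, ls, le)),
                      substr(template, le + 1L, b)),
    "single-top" = paste0(substr(template, a, s + k - 1L),
                          revcomp(substr(template, a, le))),
    "single-bottom" = paste0(revcomp(substr(template, e - k - l + 1L, b)),
                             substr(template, e - k + 1L, b)))
  if (anyDuplicated(refs))
    stop("degenerate element: classification references are not unique ",
         "(is the loop its own reverse complement?)")
  structure(list(element = element, flank = as.integer(flank), refs = refs),
            class = "inversion_quad")
}

classify_fallback <- function(seqs, quad, min_coverage = 0.95) {
  n <- length(seqs)
  hits <- matrix(FALSE, n, 4L,
                 dimnames = list(NULL, names(quad$refs)))
  dss <- Biostrings::DNAStringSet(seqs)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -6)
  for (j in seq_along(quad$refs)) {
    ref <- quad$refs[[j]]
    pa <- Biostrings::pairwiseAlignment(dss, Biostrings::DNAString(ref),
                                        type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 8, gapExtension = 4)
    cov <- Biostrings::width(Biostrings::subject(pa)) / nchar(ref)
    nid <- Biostrings::nindel(pa)
    nind <- nid@insertion[, "Length"] + nid@deletion[, "Length"]
    hits[, j] <- Biostrings::nmismatch(pa) == 0 & nind == 0 &
      cov > min_coverage
  }
  hits
}

#' Classify reads at an inverted-repeat element
#'
#' @param seqs Character vector of read sequences (reference orientation).
#' @param quad An `inversion_quad` from [build_inversion_references()].
#' @param min_coverage Required coverage of the matched reference (strictly
#'   greater than; default 0.95).
#' @return Character vector of labels: one of the four classes, or
#'   `"unassigned"` when no reference — or more than one — satisfies the
#'   zero-mismatch coverage rule.
#' @export
classify_inversion_reads <- function(seqs, quad, min_coverage = 0.95) {
  stopifnot(inherits(quad, "inversion_quad"))
  n <- length(seqs)
  if (!n) return(character(0))
  dss <- Biostrings::DNAStringSet(seqs)
  hits <- vapply(names(quad$refs), function(nm) {
    Biostrings::vcountPattern(quad$refs[[nm]], dss, fixed = TRUE) > 0L
  }, logical(n))
  if (n == 1L) hits <- matrix(hits, 1L, dimnames = list(NULL,
                                                        names(quad$refs)))
  nh <- rowSums(hits)
  out <- rep("unassigned", n)
  one <- nh == 1L
  out[one] <- colnames(hits)[max.col(hits[one, , drop = FALSE] * 1L)]
  none <- which(nh == 0L)
  if (length(none)) {
    fb <- classify_fallback(seqs[none], quad, min_coverage)
    nf <- rowSums(fb)
    onef <- nf == 1L
    out[none[onef]] <- colnames(fb)[max.col(fb[onef, , drop = FALSE] * 1L)]
  }
  out
}

#' @rdname classify_inversion_reads
#' @param seq A single read sequence.
#' @export
classify_inversion_read <- function(seq, quad, min_coverage = 0.95) {
  classify_inversion_reads(seq, quad, min_coverage)
}

#' Scan reads for template-switching at inverted-repeat elements
#'
#' Classifies every read passing the pass-count requirement against the four
#' references of each annotated element and tabulates calls per element,
#' class and strand.
#'
#' @param reads Read table.
#' @param templates A [template_set()] with a `structured` entry and
#'   element annotations.
#' @param flank Reference flank in bases (default 30).
#' @param min_passes Minimum consensus passes (default 3).
#' @return An object of class `inversion_scan`: `calls` (data.frame:
#'   `element`, `strand`, `class`, `count`), `total_scanned`, `quads`.
#' @export
scan_inversions <- function(reads, templates, flank = 30L, min_passes = 3L) {
  stopifnot(inherits(templates, "template_set"))
  if (is.null(templates$elements))
    stop("template set carries no inverted-repeat elements")
  st <- names(templates$roles)[templates$roles == "structured"]
  keep <- reads$n_passes >= min_passes
  reads <- reads[keep, , drop = FALSE]
  quads <- lapply(templates$elements, function(el)
    build_inversion_references(templates$sequences[[st]], el, flank))
  calls <- list()
  for (ei in seq_along(quads)) {
    lab <- classify_inversion_reads(reads$sequence, quads[[ei]])
    tab <- as.data.frame(table(
      strand = factor(reads$strand, levels = c("+", "-")),
      class = factor(lab, levels = c(INVERSION_CLASSES, "unassigned"))),
      stringsAsFactors = FALSE)
    tab$element <- ei
    calls[[ei]] <- tab[, c("element", "strand", "class", "Freq")]
  }
  calls <- do.call(rbind, calls)
  names(calls)[names(calls) == "Freq"] <- "count"
  structure(list(calls = calls, total_scanned = nrow(reads),
                 quads = quads),
            class = "inversion_scan")
}

#' Inversion percentages per element
#'
#' @param scan An `inversion_scan` from [scan_inversions()].
#' @return A data.frame with, per element: counts per inversion class,
#'   total scanned reads, and `pct_inversions` — the percentage of scanned
#'   reads carrying any switch class (reported as `"n.d."` in printed
#'   output when zero).
#' @export
inversion_rates <- function(scan) {
  stopifnot(inherits(scan, "inversion_scan"))
  if (scan$total_scanned == 0L)
    stop("undefined inversion rate: no reads scanned")
  sw <- c("single-top", "single-bottom", "double")
  out <- lapply(split(scan$calls, scan$calls$element), function(d) {
    byclass <- tapply(d$count, d$class, sum)
    data.frame(element = d$element[1L],
               correct = byclass[["correct"]],
               single_top = byclass[["single-top"]],
               single_bottom = byclass[["single-bottom"]],
               double = byclass[["double"]],
               unassigned = byclass[["unassigned"]],
               total = scan$total_scanned,
               pct_inversions = 100 * sum(byclass[sw]) / scan$total_scanned)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.inversion_scan <- function(x, ...) {
  r <- inversion_rates(x)
  cat("Inversion scan:", x$total_scanned, "reads\n")
  for (i in seq_len(nrow(r))) {
    el <- x$quads[[r$element[i]]]$element
    pct <- if (r$pct_inversions[i] == 0) "n.d."
           else paste0(format(r$pct_inversions[i], digits = 3), "%")
    cat(sprintf(
      "  element %d (%d..%d, stem %d, loop %d): %s strands with inversions",
      r$element[i], el$start, el$end, el$stem_length, el$loop_length, pct))
    cat(sprintf(" [single-top %d, single-bottom %d, double %d]\n",
                r$single_top[i], r$single_bottom[i], r$double[i]))
  }
  invisible(x)
}
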