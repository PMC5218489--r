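# Template construction: artificial amplicons, marker-bearing homolog pairs,
# inverted-repeat carriers and plasmid fragments.

#' Inverted-repeat element annotation
#'
#' Describes a potential cruciform: two stems that are reverse complements of
#' each other separated by a loop. Coordinates are 1-based inclusive on the
#' carrying template.
#'
#' @param start First base of the proximal stem.
#' @param stem_length Stem length in bases.
#' @param loop_length Loop length in bases.
#' @return An object of class `inverted_repeat` with fields `start`, `end`,
#'   `stem_length`, `loop_length` (`end = start + 2*stem_length +
#'   loop_length - 1`).
#' @export
inverted_repeat_element <- function(start, stem_length, loop_length) {
  start <- as.integer(start)
  stem_length <- as.integer(stem_length)
  loop_length <- as.integer(loop_length)
  stopifnot(start >= 1L, stem_length >= 1L, loop_length >= 0L)
  structure(list(start = start,
                 end = start + 2L * stem_length + loop_length - 1L,
                 stem_length = stem_length,
                 loop_length = loop_length),
            class = "inverted_repeat")
}

#' Marker table for a homolog pair
#'
#' Single-base differences distinguishing two co-amplified homologs, used to
#' localize recombination crossovers.
#'
#' @param position Strictly increasing 1-based reference coordinates.
#' @param allele_a,allele_b Bases carried by homolog A and homolog B; must
#'   differ at every marker.
#' @return A `data.frame` of class `marker_table`.
#' @export
marker_table <- function(position, allele_a, allele_b) {
  position <- as.integer(position)
  if (is.unsorted(position, strictly = TRUE))
    stop("marker positions must be strictly increasing")
  if (any(allele_a == allele_b))
    stop("allele_a and allele_b must differ at every marker")
  structure(data.frame(position = position,
                       allele_a = allele_a,
                       allele_b = allele_b,
                       stringsAsFactors = FALSE),
            class = c("marker_table", "data.frame"))
}

#' Bundle reference templates with their annotations
#'
#' @param sequences Named character vector of DNA sequences (A/C/G/T only).
#' @param roles Character vector (same length/names) with values in
#'   `amplicon`, `homolog-A`, `homolog-B`, `structured`, `plasmid`.
#' @param markers Optional [marker_table()] (required to interpret a
#'   homolog pair).
#' @param elements Optional list of [inverted_repeat_element()] annotations
#'   on the `structured` template.
#' @param primer_regions Optional data.frame with `start`,`end` intervals
#'   (1-based inclusive, template coordinates) masked from error counting.
#' @return An object of class `template_set`.
#' @export
template_set <- function(sequences, roles, markers = NULL, elements = NULL,
                         primer_regions = NULL) {
  stopifnot(length(sequences) == length(roles), !is.null(names(sequences)))
  roles <- match.arg(roles,
                     c("amplicon", "homolog-A", "homolog-B", "structured",
                       "plasmid"),
                     several.ok = TRUE)
  names(roles) <- names(sequences)
  if (!is_dna(sequences))
    stop("template sequences may contain only A/C/G/T")
  ha <- names(roles)[roles == "homolog-A"]
  hb <- names(roles)[roles == "homolog-B"]
  if (length(ha) == 1L && length(hb) == 1L) {
    a <- sequences[[ha]]; b <- sequences[[hb]]
    if (nchar(a) != nchar(b))
      stop("homolog-A and homolog-B must have equal length")
    if (is.null(markers))
      stop("a homolog pair requires a marker table")
    va <- strsplit(a, "")[[1L]]; vb <- strsplit(b, "")[[1L]]
    diffs <- which(va != vb)
    if (!identical(diffs, markers$position))
      stop("homologs must differ exactly at the marker positions")
    if (!all(va[markers$position] == markers$allele_a) ||
        !all(vb[markers$position] == markers$allele_b))
      stop("marker alleles do not match the homolog sequences")
  }
  if (!is.null(elements)) {
    st <- names(roles)[roles == "structured"]
    if (length(st) != 1L)
      stop("inverted-repeat elements require exactly one 'structured' template")
    for (el in elements) {
      stopifnot(inherits(el, "inverted_repeat"))
      seq <- sequences[[st]]
      if (el$end > nchar(seq))
        stop("element extends beyond its template")
      stem1 <- substr(seq, el$start, el$start + el$stem_length - 1L)
      stem2 <- substr(seq, el$end - el$stem_length + 1L, el$end)
      if (!identical(stem2, revcomp(stem1)))
        stop("element stems are not reverse complements of each other")
    }
  }
  structure(list(sequences = sequences,
                 roles = roles,
                 markers = markers,
                 elements = elements,
                 primer_regions = primer_regions),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat("Template set:", length(x$sequences), "sequence(s)\n")
  for (nm in names(x$sequences))
    cat(sprintf("  %-12s %-10s %5d nt\n", nm, x$roles[[nm]],
                nchar(x$sequences[[nm]])))
  if (!is.null(x$markers))
    cat("  markers:", nrow(x$markers), "at",
        paste(x$markers$position, collapse = ", "), "\n")
  if (!is.null(x$elements))
    for (el in x$elements)
      cat(sprintf("  inverted repeat %d..%d (stem %d, loop %d)\n",
                  el$start, el$end, el$stem_length, el$loop_length))
  invisible(x)
}

default_primer_regions <- function(length, primer_length = 25L) {
  data.frame(start = c(1L, length - primer_length + 1L),
             end = c(primer_length, length))
}

#' Generate a marker-bearing artificial homolog pair
#'
#' Builds a random amplicon with near-equimolar base composition and no
#' homopolymer run longer than 5 bases, then derives a second homolog by
#' substituting single bases at `marker_count` near-regularly spaced marker
#' positions.
#'
#' @param length Amplicon length in bases (must be at least
#'   `10 * marker_count`).
#' @param marker_count Number of distinguishing markers (at least 2).
#' @param seed Integer seed; the pair is reproducible.
#' @param primer_length Length of the primer region masked at each end.
#' @return A [template_set()] with entries `homolog-A`/`homolog-B`, a marker
#'   table, and default primer regions.
#' @export
make_artificial_template <- function(length, marker_count, seed,
                                     primer_length = 25L) {
  length <- as.integer(length)
  marker_count <- as.integer(marker_count)
  if (marker_count < 2L)
    stop("marker_count must be at least 2")
  if (length < 10L * marker_count)
    stop("length too small for ", marker_count,
         " markers (need length >= 10 * marker_count)")
  set.seed(seed)
  a <- random_balanced_sequence(length)
  offset <- max(6L, min(30L, length %/% (2L * marker_count)))
  pos <- unique(as.integer(round(seq(offset, length - offset,
                                     length.out = marker_count))))
  if (length(pos) != marker_count || any(diff(pos) < 5L))
    stop("length too small to space ", marker_count, " markers")
  b <- a
  allele_b <- character(marker_count)
  for (k in seq_along(pos)) {
    p <- pos[k]
    for (cand in sample(setdiff(DNA_BASES, a[p]))) {
      b[p] <- cand
      if (max_local_run(b, p, 5L) <= 5L) break
      b[p] <- a[p]
    }
    if (b[p] == a[p])
      stop("could not place marker at position ", p,
           " without creating a homopolymer run")
    allele_b[k] <- b[p]
  }
  template_set(
    sequences = c("homolog-A" = paste(a, collapse = ""),
                  "homolog-B" = paste(b, collapse = "")),
    roles = c("homolog-A", "homolog-B"),
    markers = marker_table(pos, a[pos], allele_b),
    primer_regions = default_primer_regions(length, primer_length))
}

#' Generate an amplicon carrying an inverted-repeat element
#'
#' Embeds a stem-loop-stem element (distal stem = reverse complement of the
#' proximal stem) in an otherwise random balanced-composition amplicon, as a
#' substrate for template-switching simulation and detection.
#'
#' @param length Amplicon length in bases.
#' @param element_start 1-based start of the element.
#' @param stem_length,loop_length Element geometry in bases.
#' @param seed Integer seed.
#' @param primer_length Primer-region length masked at each end.
#' @return A [template_set()] with one `structured` entry and the element
#'   annotation.
#' @export
make_structured_template <- function(length, element_start, stem_length,
                                     loop_length, seed, primer_length = 25L) {
  length <- as.integer(length)
  el <- inverted_repeat_element(element_start, stem_length, loop_length)
  if (el$end > length - 5L)
    stop("element does not fit in the template")
  set.seed(seed)
  for (attempt in seq_len(100L)) {
    x <- random_balanced_sequence(length)
    stem1 <- x[el$start:(el$start + el$stem_length - 1L)]
    x[(el$end - el$stem_length + 1L):el$end] <-
      strsplit(revcomp(paste(stem1, collapse = "")), "")[[1L]]
    loop <- paste(x[(el$start + el$stem_length):
                      (el$start + el$stem_length + el$loop_length - 1L)],
                  collapse = "")
    ok <- max(rle(x)$lengths) <= 5L && !identical(loop, revcomp(loop))
    if (ok) {
      return(template_set(
        sequences = stats::setNames(paste(x, collapse = ""), "structured-1"),
        roles = "structured",
        elements = list(el),
        primer_regions = default_primer_regions(length, primer_length)))
    }
  }
  stop("could not build a structured template with the requested geometry")
}

#' Generate a plasmid-fragment template
#'
#' Random balanced-composition fragment standing in for a restriction
#' fragment of a sequenced plasmid (no amplification, used for damage and
#' background-rate studies).
#'
#' @param length Fragment length in bases.
#' @param seed Integer seed.
#' @return A [template_set()] with one `plasmid` entry and no primer regions.
#' @export
make_plasmid_template <- function(length, seed) {
  set.seed(seed)
  template_set(
    sequences = stats::setNames(
      paste(random_balanced_sequence(as.integer(length)), collapse = ""),
      "plasmid-1"),
    roles = "plasmid")
}
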