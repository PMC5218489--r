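# Low-level DNA helpers. Sequences travel as plain upper-case character
# strings; Biostrings does the heavy lifting (reverse complement, matching).

DNA_BASES <- c("A", "C", "G", "T")

# the 12 directed base changes, alphabetical; the canonical order for all
# spectrum vectors in the package
SUB_TYPES <- c("A>C", "A>G", "A>T",
               "C>A", "C>G", "C>T",
               "G>A", "G>C", "G>T",
               "T>A", "T>C", "T>G")

# complementary-pair grouping used for spectrum tables (order as reported
# for polymerase spectra: transitions first, then transversions)
SPECTRUM_PAIRS <- list(
  "A>G/T>C" = c("A>G", "T>C"),
  "G>A/C>T" = c("G>A", "C>T"),
  "A>T/T>A" = c("A>T", "T>A"),
  "A>C/T>G" = c("A>C", "T>G"),
  "G>C/C>G" = c("G>C", "C>G"),
  "G>T/C>A" = c("G>T", "C>A"))

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# complement base-wise, no reversal
complement_bases <- function(x) chartr("ACGT", "TGCA", x)

# complement a directed change, e.g. "C>T" -> "G>A"
complement_type <- function(x) chartr("ACGT", "TGCA", x)

is_dna <- function(x) all(grepl("^[ACGT]+$", x))

# longest run touching position i, inspected in a +/- w window
max_local_run <- function(x, i, w) {
  lo <- max(1L, i - w)
  hi <- min(length(x), i + w)
  max(rle(x[lo:hi])$lengths)
}

# Swap bases until no homopolymer run exceeds max_run. Swapping (rather
# than substituting) preserves base composition exactly.
break_homopolymers <- function(x, max_run = 5L) {
  repeat {
    r <- rle(x)
    bad <- which(r$lengths > max_run)
    if (!length(bad)) return(x)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i <- starts[bad[1L]] + max_run
    done <- FALSE
    for (attempt in seq_len(2000L)) {
      j <- sample.int(length(x), 1L)
      if (x[j] == x[i]) next
      y <- x
      y[c(i, j)] <- x[c(j, i)]
      if (max_local_run(y, i, max_run) <= max_run &&
          max_local_run(y, j, max_run) <= max_run) {
        x <- y
        done <- TRUE
        break
      }
    }
    if (!done)
      stop("could not eliminate homopolymer runs > ", max_run,
           "; sequence too short or composition too constrained")
  }
}

# Random sequence with base counts as equal as possible (each base frequency
# within 1/length of 0.25) and no homopolymer run longer than max_run.
random_balanced_sequence <- function(length, max_run = 5L) {
  n4 <- length %/% 4L
  pool <- rep(DNA_BASES, n4)
  rem <- length - 4L * n4
  if (rem > 0) pool <- c(pool, sample(DNA_BASES, rem))
  x <- sample(pool)
  break_homopolymers(x, max_run)
}

# positions of each base in a sequence string -> named list of integer vecs
base_positions <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  lapply(stats::setNames(nm = DNA_BASES), function(b) which(v == b))
}

# per-base quality characters: QV (0..93) in SAM Phred+33 encoding
qv_char <- function(qv) intToUtf8(qv + 33L, multiple = FALSE)
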