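# File interchange: FASTA via Biostrings, SAM text out (plain records),
# SAM in via Rsamtools (asBam + scanBam). Consensus pass counts travel in
# the integer tag `np`; per-base qualities in the QUAL column.

#' Write simulated reads to FASTA, SAM and a truth TSV
#'
#' The SAM carries the truth alignment of each read against its template of
#' origin (MAPQ 254, maximum per-base quality 93 unless the read table says
#' otherwise, pass count in tag `np`). Structurally rearranged products
#' (inversion classes) are emitted unmapped.
#'
#' @param sim A `sim_result` from [simulate_amplification()] (or any list
#'   with compatible `reads`/`truth` data frames).
#' @param templates The [template_set()] the reads were simulated from.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"sim"`).
#' @return Invisibly, a named character vector of the paths written
#'   (`fasta`, `sam`, `truth`, `templates`).
#' @export
emit_reads <- function(sim, templates, dir, prefix = "sim") {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  reads <- sim$reads
  paths <- c(fasta = file.path(dir, paste0(prefix, "-reads.fasta")),
             sam = file.path(dir, paste0(prefix, "-reads.sam")),
             truth = file.path(dir, paste0(prefix, "-truth.tsv")),
             templates = file.path(dir, paste0(prefix, "-templates.fasta")))
  tpl <- Biostrings::DNAStringSet(templates$sequences)
  Biostrings::writeXStringSet(tpl, paths[["templates"]])
  rs <- Biostrings::DNAStringSet(stats::setNames(reads$sequence,
                                                 reads$read_id))
  Biostrings::writeXStringSet(rs, paths[["fasta"]])
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(templates$sequences),
                      nchar(templates$sequences)),
              "@PG\tID:pcrfidelity\tPN:pcrfidelity")
  if (nrow(reads)) {
    flag <- ifelse(reads$aligned, ifelse(reads$strand == "-", 16L, 0L), 4L)
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tnp:i:%d",
                    reads$read_id, flag,
                    ifelse(reads$aligned, reads$ref, "*"),
                    ifelse(reads$aligned, reads$pos, 0L),
                    ifelse(reads$aligned, reads$mapq, 0L),
                    ifelse(reads$aligned, reads$cigar, "*"),
                    reads$sequence, reads$qual, reads$n_passes)
  } else body <- character(0)
  writeLines(c(header, body), paths[["sam"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read strand-specific consensus reads from a SAM file
#'
#' Parses records written by [emit_reads()] (or any SAM with per-base
#' qualities and an `np` pass-count tag) into the read table the analysis
#' functions consume.
#'
#' @param path Path to a SAM (or BAM) file.
#' @return A data.frame with columns `read_id`, `ref`, `strand`, `pos`,
#'   `cigar`, `sequence`, `n_passes`, `mapq`, `qual`, `aligned`.
#' @export
read_consensus_sam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- if (grepl("\\.bam$", path)) path
         else Rsamtools::asBam(path,
                               destination = tempfile(fileext = ""),
                               overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq",
             "qual"),
    tag = "np")
  r <- Rsamtools::scanBam(bam, param = p)[[1L]]
  unmapped <- bitwAnd(r$flag, 4L) != 0L
  minus <- bitwAnd(r$flag, 16L) != 0L
  np <- r$tag$np
  if (is.null(np)) np <- rep(NA_integer_, length(r$qname))
  data.frame(read_id = r$qname,
             ref = as.character(r$rname),
             strand = ifelse(minus, "-", "+"),
             pos = r$pos,
             cigar = r$cigar,
             sequence = as.character(r$seq),
             n_passes = np,
             mapq = r$mapq,
             qual = as.character(r$qual),
             aligned = !unmapped,
             stringsAsFactors = FALSE)
}
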