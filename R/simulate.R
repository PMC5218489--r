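# PCR-process simulation. Two modes share a configuration:
#  * closed-form: per-read event counts are Poisson with per-base mean
#    f = n*e/2 (the first-order propagation model), positions uniform over
#    eligible bases, identities drawn from the directed spectrum;
#  * lineage-explicit: a branching process in which each molecule replicates
#    with probability efficiency_per_cycle each cycle, every replication
#    draws fresh errors, and damage hits every molecule every cycle.
# Reads and events are represented in reference orientation (SAM
# convention); the strand label records which strand the consensus covers,
# and substitution/damage identities are drawn in synthesis-strand
# orientation, then complemented onto the reference for minus-strand reads.

#' Build a template-switching replication product
#'
#' Returns the full-length product of replicating `template` across an
#' inverted-repeat element for a given read class:
#' `correct` is the faithful product; `double` (a switch onto the opposite
#' strand at the loop and back at the distal stem) reverse-complements the
#' loop in place, leaving the stems unchanged; `single-top` /
#' `single-bottom` switch once and continue on the opposite strand back
#' toward the end they came from, yielding truncated fold-back products
#' whose length differs from the full amplicon.
#'
#' @param template Template sequence (character string).
#' @param element An [inverted_repeat_element()] annotated on `template`.
#' @param cls One of `correct`, `single-top`, `single-bottom`, `double`.
#' @return The product sequence (character string, reference orientation).
#' @export
make_inversion_read <- function(template, element, cls) {
  stopifnot(inherits(element, "inverted_repeat"))
  L <- nchar(template)
  if (element$end > L) stop("element lies outside the template")
  s <- element$start; e <- element$end; k <- element$stem_length
  ls <- s + k                      # loop start
  le <- s + k + element$loop_length - 1L   # loop end
  switch(cls,
    "correct" = template,
    "double" = paste0(substr(template, 1L, ls - 1L),
                      revcomp(substr(template, ls, le)),
                      substr(template, le + 1L, L)),
    "single-top" = paste0(substr(template, 1L, s + k - 1L),
                          revcomp(substr(template, 1L, le))),
    "single-bottom" = paste0(revcomp(substr(template, e - k - element$loop_length + 1L, L)),
                             substr(template, e - k + 1L, L)),
    stop("unknown inversion class: ", cls))
}

empty_reads <- function() {
  data.frame(read_id = character(0), ref = character(0),
             strand = character(0), pos = integer(0), cigar = character(0),
             sequence = character(0), n_passes = integer(0),
             mapq = integer(0), qual = character(0), aligned = logical(0),
             stringsAsFactors = FALSE)
}

empty_truth <- function() {
  data.frame(read_id = character(0), template = character(0),
             strand = character(0), kind = character(0), pos = integer(0),
             detail = character(0), stringsAsFactors = FALSE)
}

# apply deletions/insertions to an already-substituted reference-length
# string; returns the read sequence and its reference-forward CIGAR
apply_indels <- function(seq, del_pos, ins_pos, ins_base) {
  L <- nchar(seq)
  del_pos <- sort(unique(del_pos))
  o <- order(ins_pos)
  ins_pos <- ins_pos[o]; ins_base <- ins_base[o]
  ev <- rbind(
    if (length(del_pos)) data.frame(pos = del_pos, kind = "D", base = ""),
    if (length(ins_pos)) data.frame(pos = ins_pos, kind = "I",
                                    base = ins_base))
  ev <- ev[order(ev$pos, ev$kind), , drop = FALSE]  # D sorts before I at ties
  pieces <- character(0); ops <- character(0); lens <- integer(0)
  push <- function(op, len) {
    if (len <= 0L) return()
    nops <- length(ops)
    if (nops && ops[nops] == op) lens[nops] <<- lens[nops] + len
    else { ops[nops + 1L] <<- op; lens[nops + 1L] <<- len }
  }
  cur <- 1L
  for (r in seq_len(nrow(ev))) {
    p <- ev$pos[r]
    if (ev$kind[r] == "D") {
      if (p >= cur) {
        push("M", p - cur)
        if (p > cur) pieces <- c(pieces, substr(seq, cur, p - 1L))
        push("D", 1L)
        cur <- p + 1L
      }
    } else {   # insertion after reference base p (p may be 0)
      if (p >= cur - 1L) {
        push("M", p - cur + 1L)
        if (p >= cur) pieces <- c(pieces, substr(seq, cur, p))
        push("I", 1L)
        pieces <- c(pieces, ev$base[r])
        cur <- p + 1L
      }
    }
  }
  push("M", L - cur + 1L)
  if (cur <= L) pieces <- c(pieces, substr(seq, cur, L))
  list(seq = paste(pieces, collapse = ""),
       cigar = paste0(lens, ops, collapse = ""))
}

#' Simulate PCR amplification and consensus sequencing
#'
#' Produces strand-specific consensus-like reads over the templates together
#' with a ground-truth table of every introduced event (substitution, indel,
#' damage, recombination switch, inversion-class product). Closed-form mode
#' (when `target_doublings` is set) draws per-read event counts from the
#' propagation model `f = n*e/2`; lineage mode (when `efficiency_per_cycle`
#' is set) runs the branching process explicitly.
#'
#' @param templates A [template_set()].
#' @param config A [simulation_config()].
#' @return A list of class `sim_result` with elements `reads` (data.frame:
#'   `read_id`, `ref`, `strand`, `pos`, `cigar`, `sequence`, `n_passes`,
#'   `mapq`, `qual`, `aligned`) and `truth` (data.frame: `read_id`,
#'   `template`, `strand`, `kind`, `pos`, `detail`), plus attribute
#'   `doublings` (realized in lineage mode, configured in closed form).
#' @export
simulate_amplification <- function(templates, config) {
  stopifnot(inherits(templates, "template_set"),
            inherits(config, "simulation_config"))
  if (!is.null(config$target_doublings))
    sim_closed_form(templates, config)
  else
    sim_lineage(templates, config)
}

# choose, per read and element, an inversion class
draw_inversion_classes <- function(nr, probs) {
  cls <- c("single-top", "single-bottom", "double")
  p <- stats::setNames(numeric(3L), cls)
  p[names(probs)] <- probs
  sample(c("correct", cls), nr, replace = TRUE,
         prob = c(1 - sum(p), unname(p)))
}

sim_closed_form <- function(templates, cfg) {
  set.seed(cfg$seed)
  n <- cfg$target_doublings
  if (n * cfg$sub_rate_per_doubling >= 0.1)
    warning("n * e >= 0.1: the linear propagation model f = n*e/2 is a ",
            "first-order approximation and will be biased at this load")
  seqs <- templates$sequences
  ents <- names(seqs)
  L <- nchar(seqs)
  f_sub <- n * cfg$sub_rate_per_doubling / 2
  f_del <- n * cfg$del_rate_per_doubling / 2
  f_ins <- n * cfg$ins_rate_per_doubling / 2
  f_re  <- n * cfg$recomb_rate_per_doubling / 2
  f_dam <- if (cfg$damage_rate_per_cycle > 0)
    1 - (1 - cfg$damage_rate_per_cycle)^cfg$n_cycles else 0

  nr <- cfg$n_reads
  if (nr == 0L)
    return(structure(list(reads = empty_reads(), truth = empty_truth()),
                     class = "sim_result", doublings = n))
  tpl <- sample(ents, nr, replace = TRUE)
  strand <- sample(c("+", "-"), nr, replace = TRUE)
  Lr <- L[tpl]
  k_sub <- stats::rpois(nr, f_sub * Lr)
  k_del <- stats::rpois(nr, f_del * Lr)
  k_ins <- stats::rpois(nr, f_ins * Lr)
  k_dam <- stats::rpois(nr, f_dam * Lr)
  homologs <- ents[templates$roles %in% c("homolog-A", "homolog-B")]
  k_sw <- if (f_re > 0) stats::rpois(nr, f_re * Lr) else integer(nr)

  inv_cls <- rep("correct", nr)
  inv_el <- rep(NA_integer_, nr)
  if (!is.null(templates$elements) && !is.null(cfg$inversion_probs)) {
    st <- ents[templates$roles == "structured"]
    on_st <- tpl %in% st
    for (ei in seq_along(templates$elements)) {
      todo <- which(on_st & inv_cls == "correct")
      if (!length(todo)) break
      inv_cls[todo] <- draw_inversion_classes(length(todo),
                                              cfg$inversion_probs)
      inv_el[todo[inv_cls[todo] != "correct"]] <- ei
    }
  }

  bpos <- lapply(seqs, base_positions)   # per template, ref orientation
  tpl_chars <- NULL                       # lazily split homolog sequences

  sequence <- unname(seqs[tpl])
  cigar <- paste0(Lr, "M")
  aligned <- rep(TRUE, nr)

  # truth accumulators (vectors per column, grown as lists)
  acc <- list(id = list(), kind = list(), pos = list(), detail = list(),
              i = 0L)
  add_truth <- function(id, kind, pos, detail) {
    if (!length(pos)) return()
    acc$i <<- acc$i + 1L
    acc$id[[acc$i]] <<- rep(id, length(pos))
    acc$kind[[acc$i]] <<- rep(kind, length.out = length(pos))
    acc$pos[[acc$i]] <<- as.integer(pos)
    acc$detail[[acc$i]] <<- detail
  }

  ids <- sprintf("read%06d", seq_len(nr))
  work <- which(k_sub + k_del + k_ins + k_dam + k_sw > 0 |
                  inv_cls != "correct")
  for (i in work) {
    t <- tpl[i]; Li <- Lr[i]; id <- ids[i]
    if (inv_cls[i] != "correct") {
      el <- templates$elements[[inv_el[i]]]
      sequence[i] <- make_inversion_read(seqs[[t]], el, inv_cls[i])
      cigar[i] <- "*"
      aligned[i] <- FALSE
      add_truth(id, "inversion", el$start, inv_cls[i])
      next
    }
    s <- seqs[[t]]
    pidx <- bpos[[t]]
    # recombination switches first: they define the template mosaic
    if (k_sw[i] > 0) {   # with no second homolog family every switch is cryptic
      sp <- sort(sample.int(Li - 1L, min(k_sw[i], Li - 1L)))
      partner <- sample(if (length(homologs) >= 2L) homologs else t,
                        length(sp), replace = TRUE)
      fams <- c(t, partner)
      segs_start <- c(1L, sp + 1L)
      segs_end <- c(sp, Li)
      keep <- segs_start <= segs_end
      pieces <- substring(seqs[fams[keep]], segs_start[keep], segs_end[keep])
      s <- paste(pieces, collapse = "")
      add_truth(id, "recomb_switch", sp,
                paste0(fams[-length(fams)], ">", fams[-1L]))
      if (any(fams[-length(fams)] != fams[-1L]))
        pidx <- base_positions(s)
    }
    # substitutions and damage: type first (directed spectrum), then a
    # position uniform among bases of the source type
    sub_t <- if (k_sub[i] > 0)
      sample(SUB_TYPES, k_sub[i], replace = TRUE,
             prob = cfg$sub_spectrum) else character(0)
    dam_t <- if (k_dam[i] > 0)
      sample(SUB_TYPES, k_dam[i], replace = TRUE,
             prob = cfg$damage_spectrum) else character(0)
    types <- c(sub_t, dam_t)
    kinds <- rep(c("sub", "damage"), c(length(sub_t), length(dam_t)))
    if (length(types)) {
      rtypes <- if (strand[i] == "-") complement_type(types) else types
      src <- substr(rtypes, 1L, 1L)
      alt <- substr(rtypes, 3L, 3L)
      pos <- vapply(src, function(b) {
        cand <- pidx[[b]]
        if (!length(cand)) NA_integer_ else cand[sample.int(length(cand), 1L)]
      }, integer(1L), USE.NAMES = FALSE)
      ok <- !is.na(pos) & !duplicated(pos)
      types <- types[ok]; kinds <- kinds[ok]
      pos <- pos[ok]; alt <- alt[ok]; rtypes <- rtypes[ok]
    } else pos <- integer(0)
    # deletions/insertions
    dp <- if (k_del[i] > 0) sort(sample.int(Li, min(k_del[i], Li)))
          else integer(0)
    ip <- if (k_ins[i] > 0) sample(0:Li, k_ins[i], replace = TRUE)
          else integer(0)
    ib <- if (length(ip)) sample(DNA_BASES, length(ip), replace = TRUE)
          else character(0)
    if (length(dp) && length(pos)) {
      keep <- !(pos %in% dp)   # a substituted base that is deleted vanishes
      types <- types[keep]; kinds <- kinds[keep]
      pos <- pos[keep]; alt <- alt[keep]; rtypes <- rtypes[keep]
    }
    for (j in seq_along(pos)) substr(s, pos[j], pos[j]) <- alt[j]
    if (length(pos)) add_truth(id, kinds, pos, rtypes)
    if (length(dp) || length(ip)) {
      del_base <- if (length(dp)) substring(seqs[[t]], dp, dp)
                  else character(0)
      res <- apply_indels(s, dp, ip, ib)
      s <- res$seq
      cigar[i] <- res$cigar
      add_truth(id, "del", dp, del_base)
      add_truth(id, "ins", ip, ib)
    }
    sequence[i] <- s
  }

  reads <- data.frame(
    read_id = ids, ref = tpl, strand = strand, pos = 1L, cigar = cigar,
    sequence = sequence,
    n_passes = sample(cfg$read_pass_model[1L]:cfg$read_pass_model[2L], nr,
                      replace = TRUE),
    mapq = 254L, qual = strrep("~", nchar(sequence)), aligned = aligned,
    stringsAsFactors = FALSE)
  truth <- if (acc$i == 0L) empty_truth() else {
    tid <- unlist(acc$id, use.names = FALSE)
    data.frame(read_id = tid,
               template = tpl[match(tid, ids)],
               strand = strand[match(tid, ids)],
               kind = unlist(acc$kind, use.names = FALSE),
               pos = unlist(acc$pos, use.names = FALSE),
               detail = unlist(acc$detail, use.names = FALSE),
               stringsAsFactors = FALSE)
  }
  structure(list(reads = reads, truth = truth), class = "sim_result",
            doublings = n)
}

# ---- lineage-explicit branching process ------------------------------------

new_molecule <- function(template) {
  list(template = template, cls = "correct", el = NA_integer_,
       seg_start = 1L, seg_fam = template,
       sub_pos = integer(0), sub_alt = character(0), sub_kind = character(0),
       del_pos = integer(0), ins_pos = integer(0), ins_base = character(0),
       sw_pos = integer(0), sw_from = character(0), sw_to = character(0))
}

sim_lineage <- function(templates, cfg) {
  set.seed(cfg$seed)
  seqs <- templates$sequences
  ents <- names(seqs)
  L <- nchar(seqs)
  bpos <- lapply(seqs, base_positions)
  homologs <- ents[templates$roles %in% c("homolog-A", "homolog-B")]
  st <- ents[templates$roles == "structured"]

  n0 <- cfg$initial_molecules
  pop <- vector("list", n0)
  tpl0 <- sample(ents, n0, replace = TRUE)
  for (i in seq_len(n0)) pop[[i]] <- new_molecule(tpl0[i])

  e <- cfg$sub_rate_per_doubling
  dl <- cfg$del_rate_per_doubling
  ir <- cfg$ins_rate_per_doubling
  rr <- cfg$recomb_rate_per_doubling
  d <- cfg$damage_rate_per_cycle

  for (cycle in seq_len(cfg$n_cycles)) {
    N <- length(pop)
    repl <- which(stats::runif(N) < cfg$efficiency_per_cycle)
    for (i in repl) {
      par <- pop[[i]]
      child <- par
      Li <- L[[par$template]]
      if (par$cls == "correct") {
        if (!is.null(cfg$inversion_probs) && par$template %in% st &&
            !is.null(templates$elements)) {
          cls <- draw_inversion_classes(1L, cfg$inversion_probs)
          if (cls != "correct") {
            child$cls <- cls
            child$el <- 1L
            pop[[length(pop) + 1L]] <- child
            next
          }
        }
        if (rr > 0 && length(homologs) >= 1L) {
          ks <- stats::rbinom(1L, Li - 1L, rr)
          if (ks > 0L) {
            sp <- sort(sample.int(Li - 1L, ks))
            for (p in sp) {
              partner <- pop[[sample.int(length(pop), 1L)]]
              from <- mosaic_family_at(child, p)
              child <- splice_mosaic(child, partner, p)
              child$sw_pos <- c(child$sw_pos, p)
              child$sw_from <- c(child$sw_from, from)
              child$sw_to <- c(child$sw_to, mosaic_family_at(child, p + 1L))
            }
          }
        }
        ks <- stats::rbinom(1L, Li, e)
        if (ks > 0L) {
          tps <- sample(SUB_TYPES, ks, replace = TRUE,
                        prob = cfg$sub_spectrum)
          src <- substr(tps, 1L, 1L)
          p <- vapply(src, function(b) {
            cand <- bpos[[par$template]][[b]]
            if (!length(cand)) NA_integer_
            else cand[sample.int(length(cand), 1L)]
          }, integer(1L), USE.NAMES = FALSE)
          keep <- !is.na(p)
          child$sub_pos <- c(child$sub_pos, p[keep])
          child$sub_alt <- c(child$sub_alt, substr(tps[keep], 3L, 3L))
          child$sub_kind <- c(child$sub_kind, rep("sub", sum(keep)))
        }
        kd <- stats::rbinom(1L, Li, dl)
        if (kd > 0L)
          child$del_pos <- unique(c(child$del_pos, sample.int(Li, kd)))
        ki <- stats::rbinom(1L, Li, ir)
        if (ki > 0L) {
          child$ins_pos <- c(child$ins_pos, sample(0:Li, ki, replace = TRUE))
          child$ins_base <- c(child$ins_base,
                              sample(DNA_BASES, ki, replace = TRUE))
        }
      }
      pop[[length(pop) + 1L]] <- child
    }
    if (d > 0) {
      for (i in seq_along(pop)) {
        m <- pop[[i]]
        if (m$cls != "correct") next
        kd <- stats::rbinom(1L, L[[m$template]], d)
        if (kd == 0L) next
        tps <- sample(SUB_TYPES, kd, replace = TRUE,
                      prob = cfg$damage_spectrum)
        src <- substr(tps, 1L, 1L)
        p <- vapply(src, function(b) {
          cand <- bpos[[m$template]][[b]]
          if (!length(cand)) NA_integer_
          else cand[sample.int(length(cand), 1L)]
        }, integer(1L), USE.NAMES = FALSE)
        keep <- !is.na(p)
        m$sub_pos <- c(m$sub_pos, p[keep])
        m$sub_alt <- c(m$sub_alt, substr(tps[keep], 3L, 3L))
        m$sub_kind <- c(m$sub_kind, rep("damage", sum(keep)))
        pop[[i]] <- m
      }
    }
  }

  doublings <- log2(length(pop) / n0)
  nr <- cfg$n_reads
  pick <- if (nr > 0L) sample.int(length(pop), nr, replace = TRUE)
          else integer(0)
  reads <- empty_reads()
  acc <- list()
  if (nr > 0L) {
    ids <- sprintf("read%06d", seq_len(nr))
    strand <- sample(c("+", "-"), nr, replace = TRUE)
    sequence <- character(nr); cigar <- character(nr)
    aligned <- logical(nr); tplv <- character(nr)
    for (j in seq_len(nr)) {
      m <- pop[[pick[j]]]
      tplv[j] <- m$template
      r <- realize_molecule(m, templates, seqs)
      sequence[j] <- r$seq
      cigar[j] <- r$cigar
      aligned[j] <- r$aligned
      if (nrow(r$events)) {
        ev <- r$events
        ev$read_id <- ids[j]
        ev$template <- m$template
        ev$strand <- strand[j]
        acc[[length(acc) + 1L]] <- ev[, c("read_id", "template", "strand",
                                          "kind", "pos", "detail")]
      }
    }
    reads <- data.frame(
      read_id = ids, ref = tplv, strand = strand, pos = 1L, cigar = cigar,
      sequence = sequence,
      n_passes = sample(cfg$read_pass_model[1L]:cfg$read_pass_model[2L], nr,
                        replace = TRUE),
      mapq = 254L, qual = strrep("~", nchar(sequence)), aligned = aligned,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(acc)) do.call(rbind, acc) else empty_truth()
  rownames(truth) <- NULL
  structure(list(reads = reads, truth = truth), class = "sim_result",
            doublings = doublings, final_molecules = length(pop))
}

mosaic_family_at <- function(m, p) {
  m$seg_fam[findInterval(p, m$seg_start)]
}

# child keeps parent's mosaic through p and continues on the partner's
splice_mosaic <- function(child, partner, p) {
  keep <- child$seg_start <= p
  s1 <- child$seg_start[keep]; f1 <- child$seg_fam[keep]
  after <- partner$seg_start > p + 1L
  s2 <- c(p + 1L, partner$seg_start[after])
  f2 <- c(mosaic_family_at(partner, p + 1L), partner$seg_fam[after])
  child$seg_start <- c(s1, s2)
  child$seg_fam <- c(f1, f2)
  child
}

realize_molecule <- function(m, templates, seqs) {
  L <- nchar(seqs[[m$template]])
  if (m$cls != "correct") {
    el <- templates$elements[[m$el]]
    return(list(seq = make_inversion_read(seqs[[m$template]], el, m$cls),
                cigar = "*", aligned = FALSE,
                events = data.frame(kind = "inversion", pos = el$start,
                                    detail = m$cls,
                                    stringsAsFactors = FALSE)))
  }
  # mosaic backbone
  if (length(m$seg_start) > 1L) {
    ends <- c(m$seg_start[-1L] - 1L, L)
    s <- paste(substring(seqs[m$seg_fam], m$seg_start, ends), collapse = "")
  } else s <- seqs[[m$seg_fam]]
  ev <- list()
  # later events overwrite earlier ones at the same position
  if (length(m$sub_pos)) {
    last <- !duplicated(m$sub_pos, fromLast = TRUE)
    pos <- m$sub_pos[last]; alt <- m$sub_alt[last]; kind <- m$sub_kind[last]
    drop <- pos %in% m$del_pos |
      alt == substring(s, pos, pos)   # masked by mosaic or ancestral state
    pos <- pos[!drop]; alt <- alt[!drop]; kind <- kind[!drop]
    refb <- substring(s, pos, pos)
    for (j in seq_along(pos)) substr(s, pos[j], pos[j]) <- alt[j]
    if (length(pos))
      ev[[length(ev) + 1L]] <- data.frame(kind = kind, pos = pos,
                                          detail = paste0(refb, ">", alt),
                                          stringsAsFactors = FALSE)
  }
  cigar <- paste0(L, "M")
  if (length(m$del_pos) || length(m$ins_pos)) {
    del_base <- if (length(m$del_pos))
      substring(seqs[[m$template]], m$del_pos, m$del_pos) else character(0)
    res <- apply_indels(s, m$del_pos, m$ins_pos, m$ins_base)
    s <- res$seq; cigar <- res$cigar
    if (length(m$del_pos))
      ev[[length(ev) + 1L]] <- data.frame(kind = "del", pos = sort(m$del_pos),
                                          detail = del_base[order(m$del_pos)],
                                          stringsAsFactors = FALSE)
    if (length(m$ins_pos))
      ev[[length(ev) + 1L]] <- data.frame(kind = "ins", pos = m$ins_pos,
                                          detail = m$ins_base,
                                          stringsAsFactors = FALSE)
  }
  if (length(m$sw_pos))
    ev[[length(ev) + 1L]] <- data.frame(kind = "recomb_switch",
                                        pos = m$sw_pos,
                                        detail = paste0(m$sw_from, ">",
                                                        m$sw_to),
                                        stringsAsFactors = FALSE)
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(kind = character(0), pos = integer(0),
                            detail = character(0), stringsAsFactors = FALSE)
  list(seq = s, cigar = cigar, aligned = TRUE, events = events)
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulated consensus reads:", nrow(x$reads), "reads,",
      nrow(x$truth), "ground-truth events\n")
  cat("  doublings:", format(attr(x, "doublings"), digits = 4), "\n")
  if (nrow(x$truth)) {
    tab <- table(x$truth$kind)
    cat("  events: ",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
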