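# Pipeline orchestration: validated configs, the simulate -> filter ->
# analyze composition, machine-readable reports (TSV + JSON twins) and a
# run manifest. Identical config + seed reproduces identical report files
# byte for byte.

spectrum_from_config <- function(x, path, errs) {
  if (is.character(x) && length(x) == 1L) {
    w <- switch(x,
                "taq" = taq_spectrum(),
                "uniform" = uniform_spectrum(),
                "deamination" = deamination_spectrum(),
                NULL)
    if (is.null(w)) errs$add(path, "unknown named spectrum: ", x)
    return(w)
  }
  v <- unlist(x)
  if (is.null(names(v))) {
    errs$add(path, "spectrum must be named")
    return(NULL)
  }
  if (any(grepl("/", names(v)))) {
    names(v) <- gsub("->", ">", names(v), fixed = TRUE)
    return(tryCatch(pair_spectrum(v), error = function(e) {
      errs$add(path, conditionMessage(e)); NULL
    }))
  }
  names(v) <- gsub("->", ">", names(v), fixed = TRUE)
  msg <- check_spectrum(v[SUB_TYPES], path)
  if (length(msg)) { for (m in msg) errs$add("", m); return(NULL) }
  v[SUB_TYPES]
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), checks every
#' invariant of the simulation and filter parameters, injects defaults
#' (rates policy min_passes 15, switching policy min_passes 3, reference
#' flank 30, inversion coverage 0.95), and returns the normalized
#' configuration. All violations are reported together, each naming the
#' offending field.
#'
#' @param config Path to a YAML file, or a configuration list.
#' @return A normalized list of class `fidelity_config` with components
#'   `seed`, `template`, `simulation` (a [simulation_config()]),
#'   `analysis`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  msgs <- character(0)
  errs <- list(add = function(path, ...) {
    pre <- if (nzchar(path)) paste0(path, ": ") else ""
    msgs <<- c(msgs, paste0(pre, paste0(..., collapse = "")))
  })
  if (is.null(config$seed))
    errs$add("seed", "a seed is mandatory for reproducibility")
  tpl <- config$template
  if (is.null(tpl) || is.null(tpl$kind))
    errs$add("template.kind",
             "one of amplicon, homolog_pair, structured, plasmid")
  else if (!tpl$kind %in% c("amplicon", "homolog_pair", "structured",
                            "plasmid"))
    errs$add("template.kind", "unknown kind: ", tpl$kind)
  if (is.null(tpl$length) || !is.numeric(tpl$length) || tpl$length < 50)
    errs$add("template.length", "template length >= 50 required")
  if (identical(tpl$kind, "homolog_pair")) {
    if (is.null(tpl$marker_count) || tpl$marker_count < 2)
      errs$add("template.marker_count", "at least 2 markers required")
  }
  if (identical(tpl$kind, "structured")) {
    el <- tpl$element
    if (is.null(el$start) || is.null(el$stem_length) ||
        is.null(el$loop_length))
      errs$add("template.element",
               "start, stem_length and loop_length required")
  }
  sim <- config$simulation
  if (is.null(sim)) { sim <- list(); errs$add("simulation", "missing") }
  sub_sp <- if (!is.null(sim$sub_spectrum))
    spectrum_from_config(sim$sub_spectrum, "simulation.sub_spectrum", errs)
    else uniform_spectrum()
  dam_sp <- if (!is.null(sim$damage_spectrum))
    spectrum_from_config(sim$damage_spectrum, "simulation.damage_spectrum",
                         errs)
    else deamination_spectrum()
  ip <- sim$inversion_probs
  if (!is.null(ip)) ip <- unlist(ip)
  simcfg <- NULL
  if (!length(msgs)) {
    simcfg <- tryCatch(
      simulation_config(
        seed = config$seed,
        n_reads = if (is.null(sim$n_reads)) 1000L else sim$n_reads,
        sub_rate_per_doubling = sim$sub_rate_per_doubling %||% 0,
        sub_spectrum = sub_sp,
        del_rate_per_doubling = sim$del_rate_per_doubling %||% 0,
        ins_rate_per_doubling = sim$ins_rate_per_doubling %||% 0,
        damage_rate_per_cycle = sim$damage_rate_per_cycle %||% 0,
        damage_spectrum = dam_sp,
        n_cycles = sim$n_cycles,
        target_doublings = sim$target_doublings,
        efficiency_per_cycle = sim$efficiency_per_cycle,
        initial_molecules = sim$initial_molecules,
        recomb_rate_per_doubling = sim$recomb_rate_per_doubling %||% 0,
        inversion_probs = ip,
        read_pass_model = unlist(sim$read_pass_model %||% c(15L, 40L))),
      error = function(e) {
        errs$add("simulation", conditionMessage(e)); NULL
      })
  }
  ana <- config$analysis %||% list()
  ana$rates_mode <- ana$rates_mode %||% "composition-averaged"
  ana$flank <- ana$flank %||% 30L
  ana$min_coverage <- ana$min_coverage %||% 0.95
  ana$rates_min_passes <- ana$rates_min_passes %||% 15L
  ana$switching_min_passes <- ana$switching_min_passes %||% 3L
  if (!ana$rates_mode %in% c("composition-averaged", "plain"))
    errs$add("analysis.rates_mode", "composition-averaged or plain")
  if (length(msgs))
    stop("invalid configuration:\n  ", paste(msgs, collapse = "\n  "))
  structure(list(seed = config$seed, template = tpl, simulation = simcfg,
                 analysis = ana),
            class = "fidelity_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_templates_from_config <- function(cfg) {
  tpl <- cfg$template
  tseed <- cfg$seed + 10007L
  switch(tpl$kind,
    "homolog_pair" = make_artificial_template(
      tpl$length, tpl$marker_count, seed = tseed,
      primer_length = tpl$primer_length %||% 25L),
    "structured" = make_structured_template(
      tpl$length, tpl$element$start, tpl$element$stem_length,
      tpl$element$loop_length, seed = tseed,
      primer_length = tpl$primer_length %||% 25L),
    "plasmid" = make_plasmid_template(tpl$length, seed = tseed),
    "amplicon" = {
      set.seed(tseed)
      template_set(
        sequences = stats::setNames(
          paste(random_balanced_sequence(as.integer(tpl$length)),
                collapse = ""), "amplicon-1"),
        roles = "amplicon",
        primer_regions = default_primer_regions(
          as.integer(tpl$length), tpl$primer_length %||% 25L))
    })
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full fidelity pipeline
#'
#' Simulates reads under the configuration, applies the filters, and runs
#' every analysis the template kind supports: error rates and spectrum
#' (always), inversion scan (structured templates), recombination scan
#' (homolog pairs). Reports are written as TSV/JSON twins together with a
#' run manifest; identical config and seed give byte-identical reports.
#'
#' @param config Path to a YAML configuration or a list (see
#'   [validate_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the fitted objects (`rates`,
#'   `inversions`, `recombination`, `sim`, `templates`) and `paths` of the
#'   written reports.
#' @export
run_fidelity <- function(config, out_dir) {
  cfg <- validate_config(config)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("run_fidelity [output]: cannot create ", out_dir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("run_fidelity [", name, "]: ", conditionMessage(e),
           call. = FALSE))
  }
  templates <- stage("templates", build_templates_from_config(cfg))
  sim <- stage("simulate", simulate_amplification(templates,
                                                  cfg$simulation))
  ana <- cfg$analysis
  paths <- character(0)
  results <- list(sim = sim, templates = templates)
  n <- attr(sim, "doublings")

  mode <- if (identical(cfg$template$kind, "plasmid")) "plain"
          else ana$rates_mode
  pol <- filter_policy("rates", min_passes = ana$rates_min_passes)
  fit <- stage("rates", estimate_error_rates(
    sim$reads, templates, policy = pol,
    doublings = if (n > 0) n else NULL,
    cycles = cfg$simulation$n_cycles, mode = mode))
  results$rates <- fit
  rates_df <- data.frame(metric = names(fit$rates),
                         value = unname(unlist(fit$rates)))
  p <- file.path(out_dir, "rates.tsv"); write_tsv(rates_df, p)
  paths <- c(paths, rates = p)
  p <- file.path(out_dir, "rates.json")
  jsonlite::write_json(list(counts = unclass(fit$counts),
                            rates = fit$rates),
                       p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, rates_json = p)
  if (!is.null(fit$spectrum)) {
    sp <- data.frame(pair = names(fit$spectrum$pairs),
                     percent = unname(fit$spectrum$pairs))
    p <- file.path(out_dir, "spectrum.tsv"); write_tsv(sp, p)
    paths <- c(paths, spectrum = p)
  }
  p <- file.path(out_dir, "filter_audit.json")
  jsonlite::write_json(list(input = fit$audit$input,
                            surviving = fit$audit$surviving,
                            removed = as.list(fit$audit$removed)),
                       p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, audit = p)

  if (!is.null(templates$elements)) {
    inv <- stage("inversions", scan_inversions(
      sim$reads, templates, flank = ana$flank,
      min_passes = ana$switching_min_passes))
    results$inversions <- inv
    p <- file.path(out_dir, "inversions.tsv")
    write_tsv(inversion_rates(inv), p)
    paths <- c(paths, inversions = p)
  }
  if (!is.null(templates$markers)) {
    rec <- stage("recombination", scan_recombination(
      sim$reads, templates, doublings = n,
      min_passes = ana$switching_min_passes))
    results$recombination <- rec
    p <- file.path(out_dir, "recombination.json")
    jsonlite::write_json(list(
      N_re = rec$N_re, N_total = rec$N_total, raw_rate = rec$raw_rate,
      n = rec$n, normalized_rate = rec$normalized_rate,
      strands_with_event_pct = rec$strands_with_event_pct),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, recombination = p)
    p <- file.path(out_dir, "recombination_intervals.tsv")
    write_tsv(data.frame(interval = names(rec$per_interval),
                         events = unname(rec$per_interval)), p)
    paths <- c(paths, intervals = p)
  }

  cfgfile <- tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = cfg$seed, template = cfg$template,
                            simulation = unclass(cfg$simulation),
                            analysis = cfg$analysis),
                       cfgfile, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pcrfidelity")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfgfile)),
    doublings = n,
    reads_simulated = nrow(sim$reads),
    reads_surviving_rates_filter = fit$audit$surviving,
    truth_events = nrow(sim$truth),
    timestamp = format(Sys.time(), tz = "UTC"))
  unlink(cfgfile)
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, manifest = p)
  results$paths <- paths
  invisible(results)
}
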