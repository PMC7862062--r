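#' Default pipeline configuration
#'
#' Builds (and optionally writes as YAML) the default configuration of the
#' end-to-end synthetic benchmark pipeline: a two-molecule mock rRNA
#' reference carrying annotated Psi sites (including an 18S-like hotspot at
#' positions 105/109/119, a 28S-like hotspot spanning 3700-3732, a shared
#' two-guide site at 28S-like:1771 and a single-guide site at
#' 28S-like:4417), matched tumor/normal Psi-seq and snoRNA count cohorts,
#' and a pooled CRISPR screen time course with designated depleted targets.
#'
#' @param seed Master seed (every stage derives labeled child seeds).
#' @param path Optional path; when given the config is also written as
#'   YAML (round-trips through [validate_config()] unchanged).
#' @return A validated config object (class `snopsi_config`).
#' @export
init_config <- function(seed = 1L, path = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    stages = list(psi = TRUE, expression = TRUE, screen = TRUE,
                  integration = TRUE),
    psi = list(
      len_18s = 1800L, len_28s = 4500L,
      n_pairs = 5L, coverage = 500,
      term_efficiency = 0.8, background = 0.01,
      mean_read_length = 80, offset = 0L,
      min_coverage = 20L,
      base_stoichiometry = 0.4, tumor_delta = 0.15),
    counts = list(
      n_cd = 60L, n_haca = 40L, n_pairs = 7L, n_up = 9L,
      fold_change = 4, dispersion = 0.05, total_mapped = 2e6),
    screen = list(
      n_null_targets = 57L, n_depleted = 3L, depleted_fitness = -0.3,
      n_grnas = 3L, n_nontargeting = 50L, depth = 5e5,
      replicates = 2L, day = 9, n_perm = 1000L, fdr_threshold = 0.8),
    analysis = list(lfc_threshold = 1.5, p_threshold = 0.05))
  cfg <- validate_config(cfg)
  if (!is.null(path)) {
    yaml::write_yaml(unclass(cfg), path)
  }
  cfg
}

config_schema <- function() {
  num <- function(lo, hi) list(type = "numeric", lo = lo, hi = hi)
  int <- function(lo, hi) list(type = "integer", lo = lo, hi = hi)
  lgl <- list(type = "logical")
  list(
    seed = int(0, 2^31 - 2),
    stages = list(psi = lgl, expression = lgl, screen = lgl,
                  integration = lgl),
    psi = list(
      len_18s = int(200, 1e6), len_28s = int(4500, 1e6),
      n_pairs = int(3, 100), coverage = num(0, 1e5),
      term_efficiency = num(0, 1), background = num(0, 0.05),
      mean_read_length = num(2, 1e4), offset = int(0, 1),
      min_coverage = int(1, 1e6),
      base_stoichiometry = num(0, 1), tumor_delta = num(-1, 1)),
    counts = list(
      n_cd = int(2, 1e4), n_haca = int(10, 1e4), n_pairs = int(3, 100),
      n_up = int(0, 1e4), fold_change = num(1e-6, 1e6),
      dispersion = num(1e-6, 10), total_mapped = num(1, 1e12)),
    screen = list(
      n_null_targets = int(10, 1e5), n_depleted = int(0, 100),
      depleted_fitness = num(-0.99, 0.99), n_grnas = int(2, 6),
      n_nontargeting = int(0, 1e5), depth = num(1, 1e12),
      replicates = int(1, 10), day = num(1, 100), n_perm = int(1000, 1e6),
      fdr_threshold = num(0, 1)),
    analysis = list(lfc_threshold = num(0, 100), p_threshold = num(0, 1)))
}

#' Validate a pipeline configuration
#'
#' Accepts a config list or the path of a YAML file written by
#' [init_config()]. All violations — unknown keys (typo guard), wrong
#' types, out-of-range values — are collected and reported in one error,
#' not fail-first.
#'
#' @param config A list or a YAML file path.
#' @return The validated config, classed `snopsi_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  schema <- config_schema()
  problems <- character()
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))

  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    note("unknown top-level key(s): %s", paste(unknown, collapse = ", "))
  }
  for (section in names(schema)) {
    rule <- schema[[section]]
    if (!is.null(rule$type)) {  # scalar at top level (seed)
      check_scalar(config[[section]], section, rule, note)
      next
    }
    got <- config[[section]]
    if (is.null(got)) { note("missing section '%s'", section); next }
    if (!is.list(got)) { note("section '%s' must be a mapping", section); next }
    bad <- setdiff(names(got), names(rule))
    if (length(bad)) {
      note("unknown key(s) in '%s': %s", section, paste(bad, collapse = ", "))
    }
    for (key in names(rule)) {
      check_scalar(got[[key]], paste0(section, ".", key), rule[[key]], note)
    }
  }
  if (!length(problems)) {
    if (config$counts$n_up > config$counts$n_haca) {
      note("counts.n_up cannot exceed counts.n_haca")
    }
    if (config$counts$n_haca < 10) {
      note("counts.n_haca must be >= 10 so the demo guide map has guides")
    }
  }
  if (length(problems)) {
    abort(c("invalid pipeline configuration:", setNames(problems,
                                                        rep("x", length(problems)))))
  }
  config$seed <- as.integer(config$seed)
  structure(config, class = "snopsi_config")
}

check_scalar <- function(value, name, rule, note) {
  if (is.null(value)) { note("missing value for '%s'", name); return() }
  if (length(value) != 1L) { note("'%s' must be a single value", name); return() }
  if (rule$type == "logical") {
    if (!is.logical(value)) note("'%s' must be TRUE/FALSE", name)
    return()
  }
  if (!is.numeric(value)) { note("'%s' must be numeric", name); return() }
  if (rule$type == "integer" && value != round(value)) {
    note("'%s' must be a whole number", name); return()
  }
  if (value < rule$lo || value > rule$hi) {
    note("'%s' = %s is outside [%s, %s]", name, format(value),
         format(rule$lo), format(rule$hi))
  }
}

# The demo Psi scenario: site table + guide-target map. The first
# `n_up` H/ACA snoRNA ids guide the tumor-elevated sites (hotspots and
# the shared/single fixture sites); later ids guide unchanged sites, and
# a few sites are orphans (no guide).
demo_psi_scenario <- function(cfg) {
  n_up <- cfg$counts$n_up
  n_haca <- cfg$counts$n_haca
  # ten up-regulated guide slots, recycled over the truly up ids so every
  # guide in the map exists in the simulated cohort
  slot <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 7)
  up_idx <- if (n_up > 0) ((slot - 1) %% n_up) + 1 else slot
  up_ids <- sprintf("SNORA-sim%03d", up_idx)
  mol18 <- "18S-like"; mol28 <- "28S-like"
  up_sites <- tibble(
    molecule = c(mol18, mol18, mol18, mol28, mol28, mol28, mol28, mol28,
                 mol28, mol28),
    position = c(105L, 109L, 119L, 1771L, 1771L, 4417L, 3700L, 3711L,
                 3722L, 3732L),
    guide = up_ids,
    shifted = n_up > 0)
  n_stable <- 20L
  first_stable <- min(n_up + 1L, n_haca)
  stable_ids <- sprintf("SNORA-sim%03d",
                        first_stable:min(first_stable + 9L, n_haca))
  stable_sites <- tibble(
    molecule = rep(c(mol18, mol28), each = n_stable / 2),
    position = c(seq(300L, by = 70L, length.out = n_stable / 2),
                 seq(500L, by = 250L, length.out = n_stable / 2)),
    guide = rep(stable_ids, length.out = n_stable),
    shifted = FALSE)
  orphan_sites <- tibble(
    molecule = c(mol18, mol28, mol28),
    position = c(1500L, 4100L, 4300L),
    guide = NA_character_, shifted = FALSE)
  sites <- bind_rows(up_sites, stable_sites, orphan_sites) |>
    distinct(.data$molecule, .data$position, .data$guide,
             .keep_all = TRUE)
  # one site row per (molecule, position) for the simulator;
  # guide multiplicity lives in the map
  map <- sites |>
    filter(!is.na(.data$guide)) |>
    select("snorna_id" = "guide", "molecule", "position")
  site_cfg <- sites |>
    distinct(.data$molecule, .data$position, .keep_all = TRUE) |>
    mutate(stoichiometry = cfg$psi$base_stoichiometry) |>
    select("molecule", "position", "stoichiometry", "guide", "shifted")
  list(sites = site_cfg, map = map,
       regions = list(
         hotspot_18s = list(molecule = mol18,
                            positions = c(105L, 109L, 119L)),
         hotspot_28s = list(molecule = mol28,
                            positions = c(3700L, 3711L, 3722L, 3732L))))
}

#' Run the end-to-end synthetic benchmark pipeline
#'
#' Executes the enabled stages in dependency order — simulate the inputs,
#' quantify (Psi-ratios, snoRNA counts, screen fold changes), test
#' (per-site/region/global differential Psi, paired DE, target selection)
#' and integrate (guide-target concordance) — writing versioned TSV
#' outputs plus a machine-readable JSON run report. Re-running with the
#' same configuration and seed reproduces every output byte-identically.
#' A failing stage halts only its downstream dependents; the report marks
#' them `skipped`.
#'
#' @param config A validated config ([init_config()], [validate_config()]).
#' @param outdir Output directory (created if needed).
#' @param keep_sam Also keep the per-sample simulated SAM files (default
#'   TRUE; they are the largest outputs).
#' @return Invisibly, a list with the in-memory stage results and the
#'   report.
#' @export
run_pipeline <- function(config, outdir, keep_sam = TRUE) {
  if (!inherits(config, "snopsi_config")) config <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  chash <- config_hash(unclass(config))
  meta <- c(seed = as.character(config$seed), config = chash)
  report <- list(seed = config$seed, config_hash = chash,
                 package_version = as.character(packageVersion("snopsi")),
                 stages = list())
  results <- list()
  warnings_log <- character()
  log_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage_status <- c(simulate_psi = "pending", psi = "pending",
                    expression = "pending", screen = "pending",
                    integration = "pending")
  enabled <- c(simulate_psi = isTRUE(config$stages$psi),
               psi = isTRUE(config$stages$psi),
               expression = isTRUE(config$stages$expression),
               screen = isTRUE(config$stages$screen),
               integration = isTRUE(config$stages$integration))

  run_stage <- function(name, deps, fun) {
    if (!enabled[[name]]) { stage_status[[name]] <<- "disabled"; return(NULL) }
    if (length(deps) && any(stage_status[deps] != "ok")) {
      stage_status[[name]] <<- "skipped"
      return(NULL)
    }
    out <- tryCatch(
      withCallingHandlers(fun(), warning = log_warn),
      error = function(e) {
        stage_status[[name]] <<- "failed"
        warnings_log <<- c(warnings_log,
                           sprintf("stage %s failed: %s", name,
                                   conditionMessage(e)))
        NULL
      })
    if (stage_status[[name]] == "pending") stage_status[[name]] <<- "ok"
    out
  }

  scenario <- demo_psi_scenario(config)

  ## ---- simulate + quantify Psi ------------------------------------------
  results$psi_sim <- run_stage("simulate_psi", character(), function() {
    pc <- config$psi
    psi_cfg <- sim_psi_config(
      molecules = c("18S-like" = pc$len_18s, "28S-like" = pc$len_28s),
      sites = scenario$sites[c("molecule", "position", "stoichiometry",
                               "guide")],
      term_efficiency = pc$term_efficiency, background = pc$background,
      mean_read_length = pc$mean_read_length, coverage = pc$coverage,
      offset = pc$offset, seed = derive_seed(config$seed, "psi_sim"))
    ref <- make_reference(psi_cfg, file.path(outdir, "reference.fasta"))
    write_tsv_commented(ref$sites, file.path(outdir, "psi_sites.tsv"), meta)
    # align the tumor override with the reference site order (the config
    # sorts sites by molecule/position)
    scen_key <- sprintf("%s:%d", scenario$sites$molecule,
                        scenario$sites$position)
    shifted <- scenario$sites$shifted[match(ref$sites$site_id, scen_key)]
    f_tumor <- ifelse(shifted,
                      pmin(1, pc$base_stoichiometry + pc$tumor_delta),
                      pc$base_stoichiometry)
    units <- sprintf("P%02d", seq_len(pc$n_pairs))
    sams <- list()
    for (u in units) {
      for (cond in c("T", "N")) {
        sid <- paste0(u, "_", cond)
        sam <- if (keep_sam) file.path(outdir, paste0(sid, ".sam")) else NULL
        sim <- simulate_termination_reads(
          psi_cfg, sample_id = sid, reference = ref,
          stoichiometry = if (cond == "T") f_tumor else NULL,
          sam_path = sam)
        sams[[sid]] <- sim
      }
    }
    design <- tibble(unit = units, sample_a = paste0(units, "_T"),
                     sample_b = paste0(units, "_N"))
    list(config = psi_cfg, reference = ref, sims = sams, design = design)
  })

  results$psi <- run_stage("psi", "simulate_psi", function() {
    ps <- results$psi_sim
    pc <- config$psi
    ratios <- psi_ratio_bind(lapply(names(ps$sims), function(sid) {
      prof <- build_profile(ps$sims[[sid]]$reads, ps$reference,
                            sample_id = sid)
      psi_ratio(prof, ps$reference$sites, offset = 0,
                min_coverage = pc$min_coverage)
    }))
    write_tsv_commented(ratios, file.path(outdir, "psi_ratios.tsv"), meta)
    st <- site_tests(ratios, ps$design,
                     p_threshold = config$analysis$p_threshold)
    write_tsv_commented(st, file.path(outdir, "site_tests.tsv"), meta)
    hot <- imap(scenario$regions, function(rg, nm) {
      glance(hotspot_test(ratios, ps$design, rg$molecule, rg$positions)) |>
        mutate(region = nm, .before = 1)
    }) |> bind_rows()
    write_tsv_commented(hot, file.path(outdir, "hotspot_tests.tsv"), meta)
    guided <- ps$reference$sites$site_id[!is.na(ps$reference$sites$guide)]
    shift <- global_shift_test(ratios, ps$design$sample_a,
                               ps$design$sample_b, sites = guided)
    list(ratios = ratios, site_tests = st, hotspots = hot,
         global_shift = shift)
  })

  ## ---- snoRNA expression -------------------------------------------------
  results$expression <- run_stage("expression", character(), function() {
    cc <- config$counts
    sim <- simulate_snorna_counts(sim_count_config(
      n_cd = cc$n_cd, n_haca = cc$n_haca, n_pairs = cc$n_pairs,
      n_up = cc$n_up, fold_change = cc$fold_change,
      dispersion = cc$dispersion, total_mapped = cc$total_mapped,
      seed = derive_seed(config$seed, "count_sim")))
    counts <- sim$counts |>
      left_join(select(sim$samples, "sample_id", "total_mapped"),
                by = "sample_id")
    write_tsv_commented(counts, file.path(outdir, "snorna_counts.tsv"),
                        meta)
    fr <- class_fractions(counts)
    write_tsv_commented(fr, file.path(outdir, "class_fractions.tsv"), meta)
    de <- paired_de(counts, sim$design,
                    lfc_threshold = config$analysis$lfc_threshold,
                    p_threshold = config$analysis$p_threshold)
    write_tsv_commented(de, file.path(outdir, "snorna_de.tsv"), meta)
    list(sim = sim, counts = counts, fractions = fr, de = de)
  })

  ## ---- CRISPR screen ------------------------------------------------------
  results$screen <- run_stage("screen", character(), function() {
    sc <- config$screen
    depleted <- c("SNORA65", "SNORA7A", "SNORA7B",
                  sprintf("SNORA-dep%02d", seq_len(max(0, sc$n_depleted - 3))))
    depleted <- depleted[seq_len(sc$n_depleted)]
    targets <- bind_rows(
      tibble(target_id = depleted, n_grnas = sc$n_grnas,
             fitness = sc$depleted_fitness),
      tibble(target_id = sprintf("SNO-null%03d",
                                 seq_len(sc$n_null_targets)),
             n_grnas = sc$n_grnas, fitness = 0))
    sim <- simulate_screen_counts(sim_screen_config(
      targets, n_nontargeting = sc$n_nontargeting,
      timepoints = sort(unique(c(0, 3, 5, sc$day))),
      replicates = sc$replicates, depth = sc$depth,
      seed = derive_seed(config$seed, "screen_sim")))
    write_tsv_commented(sim$counts, file.path(outdir, "screen_counts.tsv"),
                        meta)
    norm <- normalize_counts(sim$counts)
    lfc <- grna_lfc(norm, day = sc$day)
    write_tsv_commented(lfc, file.path(outdir, "grna_lfc.tsv"), meta)
    repcor <- if (sc$replicates >= 2) {
      replicate_correlation(filter(lfc, .data$replicate == 1),
                            filter(lfc, .data$replicate == 2))
    }
    sel <- aggregate_targets(lfc, n_perm = sc$n_perm,
                             seed = derive_seed(config$seed, "screen_perm"),
                             fdr_threshold = sc$fdr_threshold)
    write_tsv_commented(sel, file.path(outdir, "target_selection.tsv"),
                        meta)
    list(sim = sim, lfc = lfc, replicate_cor = repcor, selection = sel)
  })

  ## ---- integration --------------------------------------------------------
  results$integration <- run_stage(
    "integration", c("psi", "expression"), function() {
      linked <- join_results(results$expression$de,
                             results$psi$site_tests, scenario$map)
      write_tsv_commented(linked, file.path(outdir, "linked_results.tsv"),
                          meta)
      conc <- concordance_test(
        linked, mode = "fisher",
        site_p_threshold = config$analysis$p_threshold)
      list(linked = linked, concordance = conc)
    })

  ## ---- report --------------------------------------------------------------
  report$stages <- lapply(names(stage_status), function(nm) {
    list(name = nm, status = unname(stage_status[[nm]]))
  })
  report$warnings <- warnings_log
  report$record_counts <- list(
    psi_sites = if (!is.null(results$psi)) nrow(results$psi$site_tests),
    snorna = if (!is.null(results$expression))
      nrow(results$expression$de),
    grnas = if (!is.null(results$screen))
      dplyr::n_distinct(results$screen$lfc$grna_id),
    linked_rows = if (!is.null(results$integration))
      sum(results$integration$linked$link == "linked"))
  if (!is.null(results$psi)) {
    report$global_shift_p <- results$psi$global_shift$p.value
  }
  if (!is.null(results$integration)) {
    report$concordance_p <- results$integration$concordance$p.value
  }
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  results$report <- report
  invisible(results)
}
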