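#' Simulate paired tumor/normal snoRNA counts
#'
#' Draws negative-binomial counts for a matched tumor/normal design with a
#' per-patient multiplicative effect shared by both members of each pair, a
#' designated up-regulated H/ACA subset with a common true fold change, and
#' class totals calibrated to the configured shares of total mapped reads.
#'
#' @param config A [sim_count_config()].
#' @return A list of class `count_sim` with
#'   * `counts`: long tibble (`snorna_id`, `class`, `sample_id`, `count`);
#'   * `samples`: tibble (`sample_id`, `unit`, `condition`, `total_mapped`);
#'   * `design`: paired design tibble (`unit`, `sample_a`, `sample_b`) with
#'     condition A = tumor, B = normal;
#'   * `truth`: tibble (`snorna_id`, `class`, `base_mean`, `true_fc`, `up`).
#' @examples
#' sim <- simulate_snorna_counts(sim_count_config(n_cd = 20, n_haca = 10,
#'                                                seed = 7))
#' head(sim$counts)
#' @export
simulate_snorna_counts <- function(config) {
  stopifnot(inherits(config, "sim_count_config"))
  ids_cd <- sprintf("SNORD-sim%03d", seq_len(config$n_cd))
  ids_ha <- sprintf("SNORA-sim%03d", seq_len(config$n_haca))
  ids <- c(ids_cd, ids_ha)
  classes <- rep(c("CD_box", "HACA_box"), c(config$n_cd, config$n_haca))

  with_seed(derive_seed(config$seed, "snorna_counts"), {
    base <- rlnorm(length(ids), config$base_meanlog, config$base_sdlog)
    # calibrate class totals to the configured share of mapped reads
    for (cl in c("CD_box", "HACA_box")) {
      share <- if (cl == "CD_box") config$cd_share else config$haca_share
      sel <- classes == cl
      base[sel] <- base[sel] / sum(base[sel]) * share * config$total_mapped
    }
    up <- c(rep(FALSE, config$n_cd),
            seq_len(config$n_haca) <= config$n_up)
    fc <- ifelse(up, config$fold_change, 1)

    units <- sprintf("P%02d", seq_len(config$n_pairs))
    # mean-one patient effects so class-share calibration stays unbiased;
    # both are shared by the two members of a pair, so they cancel in
    # paired contrasts (the matched design's power source)
    pair_eff <- rlnorm(config$n_pairs, -config$pair_effect_sd^2 / 2,
                       config$pair_effect_sd)
    gp_eff <- matrix(rlnorm(length(ids) * config$n_pairs,
                            -config$gene_patient_sd^2 / 2,
                            config$gene_patient_sd),
                     nrow = length(ids))
    size <- 1 / config$dispersion

    counts <- vector("list", 2L * config$n_pairs)
    k <- 0L
    for (p in seq_len(config$n_pairs)) {
      for (cond in c("T", "N")) {
        k <- k + 1L
        mu <- base * pair_eff[p] * gp_eff[, p] * if (cond == "T") fc else 1
        counts[[k]] <- tibble(
          snorna_id = ids, class = classes,
          sample_id = paste0(units[p], "_", cond),
          count = rnbinom(length(ids), mu = mu, size = size))
      }
    }
    counts <- bind_rows(counts)
    samples <- counts |>
      group_by(sample_id = .data$sample_id) |>
      summarise(.groups = "drop") |>
      mutate(unit = sub("_[TN]$", "", .data$sample_id),
             condition = sub("^.*_", "", .data$sample_id),
             total_mapped = config$total_mapped)
    design <- tibble(unit = units,
                     sample_a = paste0(units, "_T"),
                     sample_b = paste0(units, "_N"))
    truth <- tibble(snorna_id = ids, class = classes, base_mean = base,
                    true_fc = fc, up = up)
    structure(list(counts = counts, samples = samples, design = design,
                   truth = truth, config = config),
              class = "count_sim")
  })
}

#' Simulate pooled CRISPR screen counts over a time course
#'
#' Each gRNA's relative abundance evolves as
#' `w0 * (1 + s)^(doublings_per_day * day)` where `s` is the fitness effect
#' of its target's knockout (0 for non-targeting controls); reads per sample
#' are drawn multinomially at the configured depth, so library totals are
#' conserved exactly. Replicates share `w0` and `s` but are sampled
#' independently.
#'
#' @param config A [sim_screen_config()].
#' @return A list of class `screen_sim` with
#'   * `counts`: long tibble (`grna_id`, `target_id`, `day`, `replicate`,
#'     `count`);
#'   * `truth`: tibble (`target_id`, `fitness`, `n_grnas`).
#' @export
simulate_screen_counts <- function(config) {
  stopifnot(inherits(config, "sim_screen_config"))
  tg <- config$targets
  grna <- tibble(
    target_id = c(rep(tg$target_id, tg$n_grnas),
                  rep("nontargeting", config$n_nontargeting)),
    fitness = c(rep(tg$fitness, tg$n_grnas),
                rep(0, config$n_nontargeting))) |>
    group_by(.data$target_id) |>
    mutate(grna_id = sprintf("%s_g%d", .data$target_id, row_number())) |>
    ungroup() |>
    select("grna_id", "target_id", "fitness")

  with_seed(derive_seed(config$seed, "screen_counts"), {
    w0 <- rlnorm(nrow(grna), 0, config$grna_sd)
    out <- list()
    for (rep_i in seq_len(config$replicates)) {
      for (day in config$timepoints) {
        w <- w0 * (1 + grna$fitness)^(config$doublings_per_day * day)
        cnt <- as.integer(rmultinom(1, size = config$depth,
                                    prob = w / sum(w)))
        out[[length(out) + 1L]] <- tibble(
          grna_id = grna$grna_id, target_id = grna$target_id,
          day = day, replicate = rep_i, count = cnt)
      }
    }
    truth <- tg |>
      select("target_id", fitness = "fitness", n_grnas = "n_grnas") |>
      bind_rows(tibble(target_id = "nontargeting", fitness = 0,
                       n_grnas = config$n_nontargeting))
    structure(list(counts = bind_rows(out), truth = truth, config = config),
              class = "screen_sim")
  })
}
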