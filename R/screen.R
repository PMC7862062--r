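#' Normalize screen counts to counts-per-million
#'
#' Per sequencing sample (one `(day, replicate)` pair), scales raw gRNA
#' counts to counts-per-million; CPM columns sum to 1e6 per sample.
#' A pseudocount of 0.5 is added only when logs are taken downstream
#' ([grna_lfc()]), never here.
#'
#' @param counts Long screen count tibble (`grna_id`, `target_id`, `day`,
#'   `replicate`, `count`).
#' @return The input with a `cpm` column added.
#' @export
normalize_counts <- function(counts) {
  assert_columns(counts, c("grna_id", "target_id", "day", "replicate",
                           "count"), "`counts`")
  sums <- counts |>
    group_by(day = .data$day, replicate = .data$replicate) |>
    summarise(libsize = sum(.data$count), .groups = "drop")
  dead <- filter(sums, .data$libsize == 0)
  if (nrow(dead)) {
    abort(sprintf("all-zero sample(s): %s",
                  paste(sprintf("day %s rep %s", dead$day, dead$replicate),
                        collapse = ", ")))
  }
  counts |>
    left_join(sums, by = c("day", "replicate")) |>
    mutate(cpm = .data$count / .data$libsize * 1e6) |>
    select(-"libsize")
}

#' Per-gRNA log2 fold change versus day 0
#'
#' `log2((cpm_t + 0.5) / (cpm_0 + 0.5))` within each replicate; day 0
#' serves as the representation of the full library before selection.
#'
#' @param normalized Output of [normalize_counts()].
#' @param day Timepoint to compare (e.g. 9).
#' @param replicate Replicate id; `NULL` (default) returns all replicates.
#' @param day0 Baseline day (default 0).
#' @return Tibble (`grna_id`, `target_id`, `replicate`, `day`, `lfc`).
#' @export
grna_lfc <- function(normalized, day, replicate = NULL, day0 = 0) {
  assert_columns(normalized, c("grna_id", "target_id", "day", "replicate",
                               "cpm"), "`normalized`")
  if (!day0 %in% normalized$day) {
    abort(sprintf("baseline day %s absent from the count table", day0))
  }
  if (!day %in% normalized$day) {
    abort(sprintf("day %s absent from the count table", day))
  }
  reps <- replicate %||% sort(unique(normalized$replicate))
  base <- normalized |>
    filter(.data$day == day0, .data$replicate %in% reps) |>
    select("grna_id", "target_id", "replicate", cpm0 = "cpm")
  later <- normalized |>
    filter(.data$day == !!day, .data$replicate %in% reps) |>
    select("grna_id", "replicate", cpm1 = "cpm")
  inner_join(base, later, by = c("grna_id", "replicate")) |>
    mutate(day = day,
           lfc = log2((.data$cpm1 + 0.5) / (.data$cpm0 + 0.5))) |>
    select("grna_id", "target_id", "replicate", "day", "lfc")
}

#' Replicate concordance of gRNA fold changes
#'
#' Pearson correlation and least-squares line between two replicates' gRNA
#' log2 fold changes over their shared gRNAs.
#'
#' @param lfc_a,lfc_b Tibbles from [grna_lfc()] (single replicate each),
#'   with `grna_id` and `lfc`.
#' @return One-row tibble: `n`, `r`, `slope`, `intercept`, `degenerate`
#'   (`TRUE` when a replicate has zero variance, in which case `r` is `NA`).
#' @export
replicate_correlation <- function(lfc_a, lfc_b) {
  shared <- inner_join(select(lfc_a, "grna_id", lfc_a = "lfc"),
                       select(lfc_b, "grna_id", lfc_b = "lfc"),
                       by = "grna_id")
  if (nrow(shared) < 10) {
    abort("need >= 10 shared gRNAs for a replicate correlation")
  }
  degenerate <- sd(shared$lfc_a) == 0 || sd(shared$lfc_b) == 0
  if (degenerate) {
    return(tibble(n = nrow(shared), r = NA_real_, slope = NA_real_,
                  intercept = NA_real_, degenerate = TRUE))
  }
  fit <- lm(lfc_b ~ lfc_a, data = shared)
  tibble(n = nrow(shared),
         r = cor(shared$lfc_a, shared$lfc_b),
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         degenerate = FALSE)
}

#' Target-level selection calls by median LFC and size-matched permutation
#'
#' Aggregates gRNA log2 fold changes to their targets: per target the
#' median gRNA LFC within each replicate, averaged over replicates. The
#' null distribution is built by drawing size-matched gRNA sets from the
#' whole library (non-targeting guides included) and aggregating them
#' identically, giving one-sided permutation p-values for depletion and
#' enrichment (lower-bounded at `1/(n_perm+1)`), Benjamini-Hochberg FDRs
#' per direction across targets, and a direction call at `fdr_threshold`.
#' This is a deliberately transparent scheme — it does not emulate any
#' published screen-analysis model's FDRs.
#'
#' @param lfc Tibble from [grna_lfc()] covering one day and all replicates.
#' @param n_perm Number of permutations (>= 1000; default 1000); the
#'   smallest attainable p-value is `1/(n_perm+1)`, so increase it when
#'   calling at stringent FDR thresholds over many targets.
#' @param seed Seed for the permutation draws.
#' @param fdr_threshold FDR at which a direction is called (default 0.8, a
#'   deliberately permissive screen-hit threshold).
#' @param control_targets Target ids never tested but kept in the
#'   permutation pool (default `"nontargeting"`).
#' @return Tibble of class `target_selection_tbl`: `target_id`, `n_grnas`,
#'   `median_lfc` (pooled), per-replicate medians in `median_lfc_rep`,
#'   `p_depleted`, `p_enriched`, `fdr_depleted`, `fdr_enriched`,
#'   `direction` (`negative`/`positive`/`none`), `status` (targets with a
#'   single gRNA are `"untested"`).
#' @export
aggregate_targets <- function(lfc, n_perm = 1000L, seed = 1L,
                              fdr_threshold = 0.8,
                              control_targets = "nontargeting") {
  assert_columns(lfc, c("grna_id", "target_id", "replicate", "lfc"),
                 "`lfc`")
  if (n_perm < 1000) abort("n_perm must be >= 1000")
  wide <- lfc |>
    select("grna_id", "target_id", "replicate", "lfc") |>
    pivot_wider(names_from = "replicate", values_from = "lfc",
                names_prefix = "rep_")
  rep_cols <- grep("^rep_", names(wide), value = TRUE)
  mat <- as.matrix(wide[rep_cols])

  pooled_stat <- function(rows) {
    mean(apply(mat[rows, , drop = FALSE], 2, median))
  }
  obs <- wide |>
    mutate(.row = row_number()) |>
    group_by(target_id = .data$target_id) |>
    summarise(n_grnas = dplyr::n(),
              median_lfc = pooled_stat(.data$.row),
              median_lfc_rep = paste(
                sprintf("%.4f", apply(mat[.data$.row, , drop = FALSE], 2,
                                      median)),
                collapse = ";"),
              .groups = "drop")

  testable <- obs$n_grnas >= 2 & !obs$target_id %in% control_targets
  sizes <- sort(unique(obs$n_grnas[testable]))
  null_by_size <- with_seed(derive_seed(seed, "target_permutation"), {
    setNames(lapply(sizes, function(k) {
      vapply(seq_len(n_perm), function(i) {
        pooled_stat(sample.int(nrow(mat), k))
      }, numeric(1))
    }), as.character(sizes))
  })

  p_dep <- p_enr <- rep(NA_real_, nrow(obs))
  for (i in which(testable)) {
    null <- null_by_size[[as.character(obs$n_grnas[i])]]
    p_dep[i] <- (1 + sum(null <= obs$median_lfc[i])) / (n_perm + 1)
    p_enr[i] <- (1 + sum(null >= obs$median_lfc[i])) / (n_perm + 1)
  }
  fdr_dep <- fdr_enr <- rep(NA_real_, nrow(obs))
  fdr_dep[testable] <- p.adjust(p_dep[testable], method = "BH")
  fdr_enr[testable] <- p.adjust(p_enr[testable], method = "BH")

  out <- obs |>
    mutate(p_depleted = p_dep, p_enriched = p_enr,
           fdr_depleted = fdr_dep, fdr_enriched = fdr_enr,
           status = dplyr::case_when(
             .data$target_id %in% control_targets ~ "control",
             .data$n_grnas < 2 ~ "untested",
             TRUE ~ "tested"),
           direction = dplyr::case_when(
             .data$status != "tested" ~ "none",
             .data$fdr_depleted <= fdr_threshold &
               .data$median_lfc < 0 &
               .data$p_depleted <= .data$p_enriched ~ "negative",
             .data$fdr_enriched <= fdr_threshold &
               .data$median_lfc > 0 ~ "positive",
             TRUE ~ "none")) |>
    arrange(.data$median_lfc)
  class(out) <- c("target_selection_tbl", class(out))
  out
}
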