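#' Two-sided Fisher exact p-value for 2x2 tables, vectorized
#'
#' Conditional exact test on the table `[a b; c d]`: with margins fixed,
#' `a` follows a hypergeometric distribution, and the two-sided p-value
#' sums all outcome probabilities not exceeding the observed one (with the
#' customary `1 + 1e-7` relative tolerance for floating-point ties). Inputs
#' are recycled and may be vectors; tables sharing margins are computed
#' once.
#'
#' @param a,b,c,d Non-negative integer cell counts (row 1: `a`, `b`;
#'   row 2: `c`, `d`).
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' fisher_exact_p(9, 1, 10, 90)
#' @export
fisher_exact_p <- function(a, b, c, d) {
  n <- length(a)
  counts <- vctrs_recycle(a, b, c, d)
  a <- counts[[1]]; b <- counts[[2]]; c <- counts[[3]]; d <- counts[[4]]
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative")
  tot <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  key <- paste(tot, r1, c1)
  p <- numeric(length(a))
  for (k in unique(key)) {
    sel <- which(key == k)
    m <- c(tot[sel[1]], r1[sel[1]], c1[sel[1]])
    lo <- max(0L, m[2] + m[3] - m[1])
    hi <- min(m[2], m[3])
    support <- lo:hi
    probs <- dhyper(support, m[3], m[1] - m[3], m[2])
    obs <- probs[match(a[sel], support)]
    p[sel] <- vapply(obs, function(po) {
      min(1, sum(probs[probs <= po * (1 + 1e-7)]))
    }, numeric(1))
  }
  p
}

# minimal common-length recycling for scalar-or-vector args
vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == len) x else rep(x, length.out = len)
  })
}

#' Join snoRNA differential expression to target-site differential
#' pseudouridylation
#'
#' Links each snoRNA's volcano-table statistics to the differential
#' Psi statistics of its annotated rRNA target sites via a guide-to-target
#' map. snoRNAs without mapped sites and sites without guides are passed
#' through with a flag rather than dropped.
#'
#' @param volcano [paired_de()] output (per-snoRNA DE statistics).
#' @param site_table [site_tests()] output (per-site differential Psi).
#' @param map Guide-target map: tibble (`snorna_id`, `molecule`,
#'   `position`), one row per (guide, site) link; a site may have several
#'   guides.
#' @return Tibble with one row per link plus flagged pass-through rows;
#'   columns `snorna_id`, `site_id`, the DE statistics (`de_lfc`, `de_p`,
#'   `de_flag`), the site statistics (`psi_delta`, `psi_lfc`, `psi_p`,
#'   `psi_significant`) and `link` (`linked`, `unmapped_snorna`,
#'   `unmapped_site`).
#' @export
join_results <- function(volcano, site_table, map) {
  assert_columns(map, c("snorna_id", "molecule", "position"), "`map`")
  assert_columns(volcano, c("snorna_id", "lfc", "p", "flag"), "`volcano`")
  assert_columns(site_table, c("site_id", "molecule", "position", "delta",
                               "lfc", "p", "significant"), "`site_table`")
  map <- map |>
    mutate(site_id = sprintf("%s:%d", .data$molecule,
                             as.integer(.data$position)))
  unknown <- setdiff(map$site_id, site_table$site_id)
  if (length(unknown)) {
    abort(c("guide-target map references unknown site(s):",
            stats::setNames(unknown, rep("x", length(unknown)))))
  }
  de <- volcano |>
    select("snorna_id", de_lfc = "lfc", de_p = "p", de_flag = "flag")
  sites <- site_table |>
    select("site_id", psi_delta = "delta", psi_lfc = "lfc", psi_p = "p",
           psi_significant = "significant")
  linked <- map |>
    inner_join(de, by = "snorna_id") |>
    inner_join(sites, by = "site_id") |>
    mutate(link = "linked")
  orphan_sno <- de |>
    anti_join(map, by = "snorna_id") |>
    mutate(link = "unmapped_snorna")
  orphan_site <- sites |>
    anti_join(map, by = "site_id") |>
    mutate(link = "unmapped_site")
  bind_rows(linked, orphan_sno, orphan_site) |>
    select(dplyr::any_of(c("snorna_id", "site_id", "molecule", "position",
                           "de_lfc", "de_p", "de_flag", "psi_delta",
                           "psi_lfc", "psi_p", "psi_significant", "link")))
}

#' Concordance between snoRNA up-regulation and target-site
#' hyper-pseudouridylation
#'
#' Tests whether rRNA sites that gained pseudouridylation in tumors
#' ("hyper-Psi": site `p < site_p_threshold` and positive delta) are
#' enriched among sites guided by up-regulated snoRNAs. The unit of
#' analysis is the distinct site; a site counts as guide-up-regulated when
#' any of its guides is flagged enriched. Modes: a 2x2 Fisher exact test
#' (default), or a label permutation that shuffles the hyper-Psi flags
#' across sites (both 2x2 margins preserved every iteration).
#'
#' @param linked [join_results()] output; only `link == "linked"` rows are
#'   used.
#' @param mode `"fisher"` or `"permutation"`.
#' @param n_perm Permutations for `mode = "permutation"` (default 10000).
#' @param seed Seed for the permutation draws.
#' @param site_p_threshold Raw-p threshold defining hyper-Psi sites.
#' @param min_sites Minimum distinct linked sites required (default 10).
#' @return A `snopsi_test` object; `glance()` exposes the 2x2 cells
#'   (`n_hyper_up`, `n_hyper_notup`, `n_nothyper_up`, `n_nothyper_notup`)
#'   and the sample odds ratio.
#' @export
concordance_test <- function(linked, mode = c("fisher", "permutation"),
                             n_perm = 10000L, seed = 1L,
                             site_p_threshold = 0.05, min_sites = 10L) {
  mode <- match.arg(mode)
  rows <- filter(linked, .data$link == "linked")
  per_site <- rows |>
    group_by(site_id = .data$site_id) |>
    summarise(hyper = any(.data$psi_p < site_p_threshold &
                            .data$psi_delta > 0),
              guide_up = any(.data$de_flag == "enriched"),
              .groups = "drop")
  m <- nrow(per_site)
  if (m < min_sites) {
    abort(sprintf("only %d linked site(s); need >= %d", m, min_sites))
  }
  a <- sum(per_site$hyper & per_site$guide_up)
  b <- sum(per_site$hyper & !per_site$guide_up)
  c_ <- sum(!per_site$hyper & per_site$guide_up)
  d <- sum(!per_site$hyper & !per_site$guide_up)
  or <- (a * d) / (b * c_)   # sample (cross-product) odds ratio
  degenerate_margin <- (a + b) %in% c(0L, m) || (a + c_) %in% c(0L, m)
  if (degenerate_margin) {
    return(new_snopsi_test(
      method = sprintf("guide-target concordance (%s)", mode),
      statistic = a, p.value = 1, n = m, estimate = or,
      estimate_name = "odds_ratio", status = "degenerate_margin",
      extra = list(n_hyper_up = a, n_hyper_notup = b, n_nothyper_up = c_,
                   n_nothyper_notup = d)))
  }
  p <- if (mode == "fisher") {
    fisher_exact_p(a, b, c_, d)
  } else {
    n_up <- a + c_
    obs <- a
    with_seed(derive_seed(seed, "concordance_permutation"), {
      hits <- vapply(seq_len(n_perm), function(i) {
        sum(sample(per_site$hyper, n_up))
      }, integer(1))
      (1 + sum(hits >= obs)) / (n_perm + 1)
    })
  }
  new_snopsi_test(
    method = sprintf("guide-target concordance (%s)", mode),
    statistic = a, p.value = p, n = m, estimate = or,
    estimate_name = "odds_ratio",
    extra = list(n_hyper_up = a, n_hyper_notup = b, n_nothyper_up = c_,
                 n_nothyper_notup = d))
}
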