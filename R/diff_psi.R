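#' Per-site paired differential pseudouridylation
#'
#' For every Psi site, compares condition A against condition B across the
#' paired design with a paired two-sided t-test (the per-site default;
#' Wilcoxon signed-rank available via `method`). Reports the mean paired
#' difference, a log2 fold change of mean ratios (pseudocount 1e-3 guards
#' fully unmodified sites), the raw p-value with a significance flag at
#' `p_threshold`, and Benjamini-Hochberg q-values across tested sites.
#' Raw-p flagging mirrors common per-site reporting in the field; q-values
#' are provided alongside for FDR-aware use.
#'
#' @param psi Long Psi-ratio tibble ([psi_ratio_bind()] output).
#' @param design Paired design tibble: `unit`, `sample_a`, `sample_b` (A is
#'   the numerator condition, e.g. tumor; B the reference, e.g. normal).
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @param p_threshold Raw-p significance threshold (default 0.05).
#' @param min_pairs Minimum complete pairs for a site to be tested
#'   (default 3); sites below it are reported with status `"untested"`.
#' @return Tibble with one row per site: `site_id`, `molecule`, `position`,
#'   `guide` (if present), `n_pairs`, `mean_a`, `mean_b`, `delta`
#'   (mean A - B difference), `lfc` (log2 of pseudocounted mean ratios),
#'   `p`, `q`, `significant`, `degenerate` (zero-variance differences) and
#'   `status`.
#' @export
site_tests <- function(psi, design, method = c("t", "wilcoxon"),
                       p_threshold = 0.05, min_pairs = 3L) {
  method <- match.arg(method)
  check_design(design, psi$sample_id)
  key_cols <- intersect(c("site_id", "molecule", "position", "guide"),
                        names(psi))
  pairs <- pair_values(psi, design, key_cols)
  out <- pairs |>
    group_by(across(dplyr::all_of(key_cols))) |>
    summarise(test_one_site(.data$value_a, .data$value_b, method,
                            min_pairs),
              .groups = "drop")
  tested <- out$status == "tested"
  out$q <- NA_real_
  out$q[tested] <- p.adjust(out$p[tested], method = "BH")
  out$significant <- tested & !is.na(out$p) & out$p < p_threshold
  out
}

check_design <- function(design, sample_ids, what = "`design`") {
  assert_columns(design, c("unit", "sample_a", "sample_b"), what)
  if (anyDuplicated(design$unit)) {
    abort("each unit must appear exactly once in the design")
  }
  missing <- setdiff(c(design$sample_a, design$sample_b),
                     unique(sample_ids))
  if (length(missing)) {
    abort(sprintf("design sample(s) absent from the data: %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(design)
}

# long psi table -> one row per (site, unit) with both conditions' values
pair_values <- function(psi, design, key_cols) {
  a <- psi |>
    inner_join(design, by = c(sample_id = "sample_a")) |>
    select(dplyr::all_of(key_cols), "unit", value_a = "psi_ratio")
  b <- psi |>
    inner_join(design, by = c(sample_id = "sample_b")) |>
    select(dplyr::all_of(key_cols), "unit", value_b = "psi_ratio")
  inner_join(a, b, by = c(key_cols, "unit"))
}

test_one_site <- function(va, vb, method, min_pairs,
                          pseudocount = 1e-3) {
  ok <- !is.na(va) & !is.na(vb)
  va <- va[ok]; vb <- vb[ok]
  n <- length(va)
  if (n < min_pairs) {
    return(tibble(n_pairs = n, mean_a = NA_real_, mean_b = NA_real_,
                  delta = NA_real_, lfc = NA_real_, p = NA_real_,
                  degenerate = FALSE, status = "untested"))
  }
  d <- va - vb
  degenerate <- isTRUE(all.equal(sd(d), 0)) || all(d == 0)
  p <- if (degenerate) {
    1
  } else if (method == "t") {
    t.test(va, vb, paired = TRUE)$p.value
  } else {
    paired_wilcoxon_p(va, vb)
  }
  tibble(n_pairs = n, mean_a = mean(va), mean_b = mean(vb),
         delta = mean(d),
         lfc = log2((mean(va) + pseudocount) / (mean(vb) + pseudocount)),
         p = p, degenerate = degenerate, status = "tested")
}

# Wilcoxon signed-rank, zero differences dropped; exact null for <= 25
# informative pairs when there are no ties among |differences|, otherwise
# the normal approximation with continuity correction. Fixed here because
# implementations differ in their switch points.
paired_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  exact <- n <= 25 && !any(duplicated(abs(d)))
  suppressWarnings(
    wilcox.test(d, exact = exact, correct = TRUE)$p.value)
}

#' Global shift test between two conditions over many sites
#'
#' Two-sided Wilcoxon signed-rank test of a transcriptome-wide shift: each
#' site contributes one paired observation, its mean value across the
#' condition-A samples versus across the condition-B samples. `sites`
#' restricts the test to a subset (e.g. only H/ACA-guided sites), which is
#' how guided and unguided site classes are dissociated after a snoRNP
#' knockdown.
#'
#' @param psi Long Psi-ratio tibble.
#' @param samples_a,samples_b Character vectors of sample ids for the two
#'   conditions.
#' @param sites Optional character vector of `site_id`s to restrict to.
#' @param min_sites Minimum paired observations required (default 6).
#' @return A `snopsi_test` object (supports [tidy()], [glance()], `print`).
#' @export
global_shift_test <- function(psi, samples_a, samples_b, sites = NULL,
                              min_sites = 6L) {
  stopifnot(length(samples_a) >= 1, length(samples_b) >= 1)
  if (!is.null(sites)) psi <- filter(psi, .data$site_id %in% sites)
  wide <- psi |>
    filter(.data$sample_id %in% c(samples_a, samples_b)) |>
    group_by(site_id = .data$site_id) |>
    summarise(
      mean_a = mean(.data$psi_ratio[.data$sample_id %in% samples_a]),
      mean_b = mean(.data$psi_ratio[.data$sample_id %in% samples_b]),
      .groups = "drop") |>
    filter(!is.na(.data$mean_a), !is.na(.data$mean_b))
  n <- nrow(wide)
  if (n < min_sites) {
    abort(sprintf(
      "only %d site(s) with complete values in both conditions (need >= %d)",
      n, min_sites))
  }
  d <- wide$mean_a - wide$mean_b
  if (all(d == 0)) {
    p <- 1
    stat <- NA_real_
  } else {
    p <- paired_wilcoxon_p(wide$mean_a, wide$mean_b)
    stat <- unname(suppressWarnings(
      wilcox.test(d[d != 0], exact = FALSE)$statistic))
  }
  new_snopsi_test(
    method = "paired Wilcoxon signed-rank (global shift)",
    statistic = unname(stat), p.value = p, n = n,
    estimate = median(d), estimate_name = "median_shift")
}

#' Paired test on summed pseudouridylation over a hotspot region
#'
#' Sums the Psi-ratios of a region's sites per sample ([region_sum()]) and
#' applies a paired two-sided t-test across units; samples with incomplete
#' regions drop their whole pair. This is the region-level analogue of the
#' per-site tests, sensitive to coordinated shifts over adjacent uridines.
#'
#' @param psi Long Psi-ratio tibble.
#' @param design Paired design (`unit`, `sample_a`, `sample_b`).
#' @param molecule,positions Region definition as in [region_sum()].
#' @return A `snopsi_test` object; `glance()` adds the per-condition mean
#'   sums and the number of complete pairs. Status is `"untested"` (p `NA`)
#'   with fewer than 3 complete pairs.
#' @export
hotspot_test <- function(psi, design, molecule, positions) {
  check_design(design, psi$sample_id)
  sums <- region_sum(psi, molecule, positions)
  lookup <- setNames(sums$region_sum, sums$sample_id)
  sa <- lookup[design$sample_a]
  sb <- lookup[design$sample_b]
  ok <- !is.na(sa) & !is.na(sb)
  n <- sum(ok)
  if (n < 3) {
    return(new_snopsi_test(
      method = "paired t on region sums", statistic = NA_real_,
      p.value = NA_real_, n = n, estimate = NA_real_,
      estimate_name = "mean_difference", status = "untested",
      extra = list(mean_sum_a = NA_real_, mean_sum_b = NA_real_)))
  }
  sa <- sa[ok]; sb <- sb[ok]
  d <- sa - sb
  if (isTRUE(all.equal(sd(d), 0))) {
    stat <- NA_real_; p <- 1
  } else {
    tt <- t.test(sa, sb, paired = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  new_snopsi_test(
    method = "paired t on region sums", statistic = stat, p.value = p,
    n = n, estimate = mean(d), estimate_name = "mean_difference",
    extra = list(mean_sum_a = mean(sa), mean_sum_b = mean(sb)))
}

new_snopsi_test <- function(method, statistic, p.value, n, estimate,
                            estimate_name, status = "tested",
                            extra = list()) {
  structure(c(list(method = method, statistic = statistic,
                   p.value = p.value, n = n, estimate = estimate,
                   estimate_name = estimate_name, status = status),
              extra),
            class = "snopsi_test")
}

#' @export
print.snopsi_test <- function(x, ...) {
  cat(sprintf("%s\n  n = %d, %s = %s, p = %s%s\n",
              x$method, x$n, x$estimate_name,
              format(x$estimate, digits = 4),
              format.pval(x$p.value, digits = 3),
              if (x$status != "tested") paste0(" [", x$status, "]") else ""))
  invisible(x)
}

#' Tidy or summarize a snopsi test result
#'
#' `tidy()` returns the core statistic/p-value row; `glance()` appends the
#' test-specific extras (2x2 cells, per-condition means, ...).
#'
#' @param x A `snopsi_test` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy snopsi_test
#' @export
tidy.snopsi_test <- function(x, ...) {
  tibble(method = x$method, estimate = x$estimate,
         estimate_name = x$estimate_name,
         statistic = x$statistic, p.value = x$p.value,
         n = x$n, status = x$status)
}

#' @rdname tidy.snopsi_test
#' @method glance snopsi_test
#' @export
glance.snopsi_test <- function(x, ...) {
  core <- tidy(x)
  extra <- x[setdiff(names(x), c(names(core), "estimate_name"))]
  extra <- extra[map_int(extra, length) == 1L &
                   !names(extra) %in% c("method", "statistic", "p.value",
                                        "n", "estimate", "status")]
  if (length(extra)) core <- bind_cols(core, as_tibble(extra))
  core
}
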