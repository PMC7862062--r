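#' Count reads per snoRNA from alignments
#'
#' Assigns each aligned read to a snoRNA when at least `min_overlap_frac`
#' of its aligned length overlaps the snoRNA interval on the same strand.
#' Reads overlapping several snoRNAs go to the one with the larger overlap;
#' exact ties are discarded (and counted). The counting rule is
#' deliberately simple and fully stated, since small-RNA quantification
#' protocols rarely publish theirs.
#'
#' @param alignments Tibble with `molecule`, `start`, `end`, `strand`
#'   (from [read_alignments()]), or a SAM/BAM path.
#' @param annotation snoRNA annotation tibble: `snorna_id`, `class`
#'   (`CD_box`, `HACA_box` or `other`), `molecule`, `start`, `end` (BED
#'   convention: 0-based half-open), `strand`; extra columns (host gene,
#'   target sites) pass through untouched.
#' @param min_overlap_frac Minimum fraction of the read's aligned length
#'   that must overlap the snoRNA (default 0.5).
#' @param sample_id Sample label for the output column.
#' @param total_mapped Total mapped reads in the library (denominator for
#'   class fractions / CPM). Defaults to the number of input alignments.
#' @return Tibble (`snorna_id`, `class`, `sample_id`, `count`,
#'   `total_mapped`) covering every annotated snoRNA (zeros included), with
#'   attributes `n_assigned`, `n_unassigned`, `n_ties`, `n_total`.
#' @export
count_snornas <- function(alignments, annotation, min_overlap_frac = 0.5,
                          sample_id = "sample", total_mapped = NULL) {
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_alignments(alignments)
  }
  assert_columns(alignments, c("molecule", "start", "end"), "`alignments`")
  assert_columns(annotation,
                 c("snorna_id", "class", "molecule", "start", "end",
                   "strand"), "`annotation`")
  if (!"strand" %in% names(alignments)) alignments$strand <- "+"
  n_total <- nrow(alignments)
  total_mapped <- total_mapped %||% n_total

  # BED 0-based half-open -> 1-based inclusive
  ann <- annotation |>
    mutate(start1 = as.integer(.data$start) + 1L,
           end1 = as.integer(.data$end))
  if (any(ann$end1 < ann$start1)) abort("annotation has end <= start")

  best_idx <- rep(NA_integer_, n_total)
  tie <- logical(n_total)
  if (n_total > 0) {
    for (key in unique(paste0(ann$molecule, "\x1f", ann$strand))) {
      parts <- strsplit(key, "\x1f", fixed = TRUE)[[1]]
      asel <- which(ann$molecule == parts[1] & ann$strand == parts[2])
      rsel <- which(alignments$molecule == parts[1] &
                      alignments$strand == parts[2])
      if (!length(asel) || !length(rsel)) next
      q <- IRanges::IRanges(alignments$start[rsel], alignments$end[rsel])
      s <- IRanges::IRanges(ann$start1[asel], ann$end1[asel])
      hits <- IRanges::findOverlaps(q, s)
      if (!length(hits)) next
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
      frac <- ov / IRanges::width(q)[qh]
      keep <- frac >= min_overlap_frac
      qh <- qh[keep]; sh <- sh[keep]; ov <- ov[keep]
      if (!length(qh)) next
      # per read: largest overlap wins, exact ties discarded
      o <- order(qh, -ov)
      qh <- qh[o]; sh <- sh[o]; ov <- ov[o]
      first <- !duplicated(qh)
      top_ov <- setNames(ov[first], qh[first])
      n_hits <- table(qh)
      second <- which(!first)
      tied_reads <- unique(qh[second][ov[second] == top_ov[as.character(qh[second])]])
      winner <- qh[first]
      best <- sh[first]
      ok <- !(winner %in% tied_reads)
      best_idx[rsel[winner[ok]]] <- asel[best[ok]]
      tie[rsel[tied_reads]] <- TRUE
    }
  }
  n_ties <- sum(tie)
  n_assigned <- sum(!is.na(best_idx))
  if (n_total > 0 && n_ties / n_total > 0.01) {
    warn(sprintf(
      "%.1f%% of reads tie between overlapping snoRNA annotations and were discarded",
      100 * n_ties / n_total))
  }
  counts <- tabulate(best_idx, nbins = nrow(ann))
  out <- tibble(snorna_id = ann$snorna_id, class = ann$class,
                sample_id = sample_id, count = counts,
                total_mapped = total_mapped)
  structure(out, n_assigned = n_assigned,
            n_unassigned = n_total - n_assigned - n_ties,
            n_ties = n_ties, n_total = n_total)
}

#' RNA-class composition of a snoRNA count table
#'
#' Per sample (and pooled over samples), the share of total mapped reads
#' captured by each snoRNA class, the remainder reported as `unassigned`
#' (other RNA species), plus the number of detected members per class.
#'
#' @param counts Long count tibble (`snorna_id`, `class`, `sample_id`,
#'   `count`) with a `total_mapped` column or a separate `totals` tibble.
#' @param totals Optional tibble (`sample_id`, `total_mapped`) overriding /
#'   supplying per-sample totals.
#' @return Tibble with `sample_id` (including `"pooled"`), `class`,
#'   `n_members`, `n_detected`, `reads`, `fraction` and `percent`; per
#'   sample the fractions (classes + unassigned) sum to 1.
#' @export
class_fractions <- function(counts, totals = NULL) {
  assert_columns(counts, c("snorna_id", "class", "sample_id", "count"),
                 "`counts`")
  if (is.null(totals)) {
    assert_columns(counts, "total_mapped",
                   "`counts` (without a `totals` table)")
    totals <- distinct(counts, .data$sample_id, .data$total_mapped)
  }
  if (any(totals$total_mapped <= 0)) {
    abort("total mapped reads must be > 0 for every sample")
  }
  per_sample <- counts |>
    select(-dplyr::any_of("total_mapped")) |>
    left_join(totals, by = "sample_id") |>
    group_by(sample_id = .data$sample_id, class = .data$class) |>
    summarise(n_members = dplyr::n(),
              n_detected = sum(.data$count > 0),
              reads = sum(.data$count),
              total = .data$total_mapped[1], .groups = "drop")
  pooled <- per_sample |>
    group_by(class = .data$class) |>
    summarise(sample_id = "pooled", n_members = max(.data$n_members),
              n_detected = max(.data$n_detected),
              reads = sum(.data$reads), total = sum(.data$total),
              .groups = "drop")
  both <- bind_rows(per_sample, pooled)
  unass <- both |>
    group_by(sample_id = .data$sample_id) |>
    summarise(class = "unassigned", n_members = NA_integer_,
              n_detected = NA_integer_,
              reads = .data$total[1] - sum(.data$reads),
              total = .data$total[1], .groups = "drop")
  bind_rows(both, unass) |>
    mutate(fraction = .data$reads / .data$total,
           percent = 100 * .data$fraction) |>
    select("sample_id", "class", "n_members", "n_detected", "reads",
           "fraction", "percent") |>
    arrange(.data$sample_id != "pooled", .data$sample_id, .data$class)
}

#' Paired differential snoRNA expression (volcano table)
#'
#' Counts are normalized to counts-per-million of total mapped reads, log2
#' transformed with pseudocount 0.5, and compared across the paired design:
#' the statistic per snoRNA is the mean per-pair log2 fold change (A/B,
#' e.g. tumor/normal) with a paired Wilcoxon signed-rank p-value (paired t
#' available via `method`). snoRNAs are flagged `enriched` when
#' `lfc > lfc_threshold` and `p < p_threshold`, `depleted` symmetrically.
#'
#' @param counts Long count tibble (`snorna_id`, `class`, `sample_id`,
#'   `count`, `total_mapped`).
#' @param design Paired design tibble (`unit`, `sample_a`, `sample_b`).
#' @param lfc_threshold log2 fold-change threshold (default 1.5).
#' @param p_threshold Raw p-value threshold (default 0.05).
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return Tibble per snoRNA: `snorna_id`, `class`, `n_pairs`, `mean_cpm_a`,
#'   `mean_cpm_b`, `lfc`, `p`, `q` (BH), `flag`
#'   (`enriched`/`depleted`/`none`). snoRNAs with zero counts in every
#'   sample are excluded (with a message).
#' @export
paired_de <- function(counts, design, lfc_threshold = 1.5,
                      p_threshold = 0.05,
                      method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  assert_columns(counts, c("snorna_id", "class", "sample_id", "count",
                           "total_mapped"), "`counts`")
  check_design(design, counts$sample_id)
  if (nrow(design) < 3) abort("need >= 3 pairs for a paired test")

  all_zero <- counts |>
    group_by(snorna_id = .data$snorna_id) |>
    summarise(dead = all(.data$count == 0), .groups = "drop") |>
    filter(.data$dead)
  if (nrow(all_zero)) {
    inform(sprintf("excluding %d snoRNA(s) with zero counts in all samples",
                   nrow(all_zero)))
    counts <- filter(counts, !.data$snorna_id %in% all_zero$snorna_id)
  }
  cpm <- counts |>
    mutate(logcpm = log2(.data$count / .data$total_mapped * 1e6 + 0.5))
  a <- cpm |>
    inner_join(design, by = c(sample_id = "sample_a")) |>
    select("snorna_id", "class", "unit", cpm_a = "logcpm")
  b <- cpm |>
    inner_join(design, by = c(sample_id = "sample_b")) |>
    select("snorna_id", "unit", cpm_b = "logcpm")
  paired <- inner_join(a, b, by = c("snorna_id", "unit"))
  out <- paired |>
    group_by(snorna_id = .data$snorna_id, class = .data$class) |>
    summarise(n_pairs = dplyr::n(),
              mean_cpm_a = mean(.data$cpm_a),
              mean_cpm_b = mean(.data$cpm_b),
              lfc = mean(.data$cpm_a - .data$cpm_b),
              p = paired_p(.data$cpm_a, .data$cpm_b, method),
              .groups = "drop") |>
    mutate(q = p.adjust(.data$p, method = "BH"),
           flag = dplyr::case_when(
             .data$lfc > lfc_threshold & .data$p < p_threshold ~ "enriched",
             .data$lfc < -lfc_threshold & .data$p < p_threshold ~ "depleted",
             TRUE ~ "none"))
  class(out) <- c("snorna_de_tbl", class(out))
  out
}

# degenerate (zero-variance) paired differences report p = 1
paired_p <- function(a, b, method) {
  d <- a - b
  if (isTRUE(all.equal(sd(d), 0))) return(1)
  if (method == "wilcoxon") paired_wilcoxon_p(a, b)
  else t.test(a, b, paired = TRUE)$p.value
}
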