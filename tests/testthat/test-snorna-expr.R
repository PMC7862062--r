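ann_fixture <- tibble::tibble(
  snorna_id = c("SNORD-a", "SNORD-b", "SNORA-a"),
  class = c("CD_box", "CD_box", "HACA_box"),
  molecule = "chr1",
  start = c(100L, 500L, 900L),     # BED: 0-based half-open
  end = c(180L, 590L, 1030L),
  strand = c("+", "+", "-"))

test_that("read assignment follows the fractional-overlap rule", {
  reads <- tibble::tibble(
    molecule = "chr1",
    start = c(110L, 120L, 95L, 910L, 910L),
    end = c(150L, 160L, 124L, 950L, 950L),
    strand = c("+", "+", "+", "-", "+"))
  # read 3: 100 nt... actually 30 nt long, overlap 101..124 = 24/30 = 0.8;
  # shrink overlap below threshold by moving start
  reads$start[3] <- 61L   # span 61..124, overlap 101..124 = 24/64 < 0.5
  cnt <- count_snornas(reads, ann_fixture, sample_id = "s1")
  expect_equal(cnt$count[cnt$snorna_id == "SNORD-a"], 2L)
  expect_equal(cnt$count[cnt$snorna_id == "SNORA-a"], 1L)  # strand-matched
  expect_equal(attr(cnt, "n_unassigned"), 2L)              # frac + strand
  expect_equal(attr(cnt, "n_assigned") + attr(cnt, "n_unassigned") +
                 attr(cnt, "n_ties"), nrow(reads))
})

test_that("multi-hit reads go to the larger overlap; exact ties are discarded", {
  ann <- tibble::tibble(
    snorna_id = c("L", "R"), class = "CD_box", molecule = "chr1",
    start = c(0L, 60L), end = c(100L, 160L), strand = "+")
  # 81-150: overlaps L by 20, R by 90 -> R
  larger <- tibble::tibble(molecule = "chr1", start = 81L, end = 150L,
                           strand = "+")
  cnt <- count_snornas(larger, ann)
  expect_equal(cnt$count[cnt$snorna_id == "R"], 1L)
  # 41-120: overlaps L by 60, R by 60 -> tie, discarded
  tied <- tibble::tibble(molecule = "chr1", start = 41L, end = 120L,
                         strand = "+")
  expect_warning(cnt2 <- count_snornas(tied, ann), "tie")
  expect_equal(sum(cnt2$count), 0L)
  expect_equal(attr(cnt2, "n_ties"), 1L)
})

test_that("reads simulated from known snoRNAs are recovered exactly", {
  set.seed(31)
  truth <- c("SNORD-a" = 40L, "SNORD-b" = 25L, "SNORA-a" = 35L)
  reads <- purrr::imap(truth, function(n, id) {
    row <- ann_fixture[ann_fixture$snorna_id == id, ]
    s <- row$start + 1L + sample.int(20, n, replace = TRUE)
    tibble::tibble(molecule = row$molecule, start = s, end = s + 29L,
                   strand = row$strand)
  }) |> dplyr::bind_rows()
  cnt <- count_snornas(reads, ann_fixture)
  expect_equal(setNames(cnt$count, cnt$snorna_id), truth)
})

test_that("class fractions conserve the library and report percentages", {
  counts <- tibble::tibble(
    snorna_id = c("SNORD-a", "SNORD-b", "SNORA-a"),
    class = c("CD_box", "CD_box", "HACA_box"),
    sample_id = "s1",
    count = c(1000L, 0L, 0L),
    total_mapped = 1000L)
  fr <- class_fractions(counts)
  one <- fr[fr$sample_id == "s1", ]
  expect_equal(one$percent[one$class == "CD_box"], 100)
  expect_equal(one$percent[one$class == "HACA_box"], 0)
  expect_equal(sum(one$fraction), 1)
  expect_equal(one$n_detected[one$class == "CD_box"], 1L)
  expect_error(class_fractions(dplyr::mutate(counts, total_mapped = 0)),
               "must be > 0")
})

test_that("simulator calibrated to the lung-tissue class shares reproduces them", {
  # no patient effect / no injected signal: isolates the share calibration
  sim <- simulate_snorna_counts(
    sim_count_config(n_up = 0L, fold_change = 1, pair_effect_sd = 0,
                     seed = 77))
  counts <- dplyr::left_join(
    sim$counts, dplyr::select(sim$samples, sample_id, total_mapped),
    by = "sample_id")
  pooled <- class_fractions(counts)
  pooled <- pooled[pooled$sample_id == "pooled", ]
  expect_equal(pooled$percent[pooled$class == "CD_box"], 16,
               tolerance = 0.1)          # relative: within ~1.6 points
  expect_equal(pooled$percent[pooled$class == "HACA_box"], 4.4,
               tolerance = 0.1)
  expect_equal(pooled$n_members[pooled$class == "CD_box"], 242L)
  expect_equal(pooled$n_members[pooled$class == "HACA_box"], 67L)
})

test_that("paired DE: identical conditions produce no flags", {
  sim <- simulate_snorna_counts(sim_count_config(
    n_cd = 30, n_haca = 15, n_up = 0, fold_change = 1, seed = 5))
  counts <- dplyr::left_join(
    sim$counts, dplyr::select(sim$samples, sample_id, total_mapped),
    by = "sample_id")
  same <- dplyr::mutate(sim$design, sample_b = sample_a)
  de <- paired_de(counts, same)
  expect_true(all(de$flag == "none"))
  expect_true(all(de$p == 1))
  expect_true(all(de$lfc == 0))
})

test_that("paired DE is antisymmetric under condition swap", {
  sim <- simulate_snorna_counts(sim_count_config(
    n_cd = 30, n_haca = 15, n_up = 5, fold_change = 4, seed = 6))
  counts <- dplyr::left_join(
    sim$counts, dplyr::select(sim$samples, sample_id, total_mapped),
    by = "sample_id")
  de1 <- paired_de(counts, sim$design)
  de2 <- paired_de(counts, dplyr::rename(sim$design,
                                         sample_a = sample_b,
                                         sample_b = sample_a))
  expect_equal(de1$lfc, -de2$lfc)
  expect_equal(de1$p, de2$p)
  expect_setequal(de1$snorna_id[de1$flag == "enriched"],
                  de2$snorna_id[de2$flag == "depleted"])
})

test_that("CPM normalization is invariant to library-size rescaling", {
  sim <- simulate_snorna_counts(sim_count_config(
    n_cd = 20, n_haca = 10, n_up = 0, fold_change = 1, seed = 8))
  counts <- dplyr::left_join(
    sim$counts, dplyr::select(sim$samples, sample_id, total_mapped),
    by = "sample_id")
  doubled <- dplyr::mutate(
    counts,
    count = ifelse(sample_id == "P01_T", count * 2L, count),
    total_mapped = ifelse(sample_id == "P01_T", total_mapped * 2,
                          total_mapped))
  expect_equal(paired_de(counts, sim$design),
               paired_de(doubled, sim$design), ignore_attr = TRUE)
})

test_that("all-zero snoRNAs are excluded with a message", {
  sim <- simulate_snorna_counts(sim_count_config(
    n_cd = 20, n_haca = 10, n_up = 0, fold_change = 1, seed = 9))
  counts <- dplyr::left_join(
    sim$counts, dplyr::select(sim$samples, sample_id, total_mapped),
    by = "sample_id")
  counts$count[counts$snorna_id == "SNORD-sim001"] <- 0L
  expect_message(de <- paired_de(counts, sim$design), "zero counts")
  expect_false("SNORD-sim001" %in% de$snorna_id)
})

test_that("designated up-regulated snoRNAs are flagged at the volcano thresholds", {
  sim <- simulate_snorna_counts(sim_count_config(seed = 101))
  counts <- dplyr::left_join(
    sim$counts, dplyr::select(sim$samples, sample_id, total_mapped),
    by = "sample_id")
  de <- paired_de(counts, sim$design)
  up <- sim$truth$snorna_id[sim$truth$up]
  flagged <- de$snorna_id[de$flag == "enriched"]
  expect_gte(sum(up %in% flagged), 8)   # >= 8 of the 9 injected
})
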