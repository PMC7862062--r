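null_screen_config <- function(seed, n_targets = 50, n_grnas = 3L,
                               depth = 2e5) {
  sim_screen_config(
    tibble::tibble(target_id = sprintf("T%03d", seq_len(n_targets)),
                   n_grnas = n_grnas, fitness = 0),
    n_nontargeting = 20L, depth = depth, seed = seed)
}

test_that("screen counts conserve depth and reproduce under the same seed", {
  cfg <- null_screen_config(1)
  sim <- simulate_screen_counts(cfg)
  per_sample <- dplyr::count(sim$counts, day, replicate, wt = count)
  expect_true(all(per_sample$n == cfg$depth))
  sim2 <- simulate_screen_counts(cfg)
  expect_identical(sim$counts, sim2$counts)
})

test_that("fitness bounds and config invariants are enforced", {
  expect_error(sim_screen_config(
    tibble::tibble(target_id = "A", n_grnas = 3L, fitness = -1)),
    "fitness")
  expect_error(sim_screen_config(
    tibble::tibble(target_id = "A", n_grnas = 8L, fitness = 0)),
    "2-6")
  expect_error(sim_screen_config(
    tibble::tibble(target_id = "A", n_grnas = 3L, fitness = 0),
    timepoints = c(3, 9)), "day 0")
})

test_that("CPM normalization: proportional samples match, totals hit 1e6", {
  counts <- tidyr::expand_grid(grna_id = sprintf("g%02d", 1:20),
                               day = c(0, 9), replicate = 1L) |>
    dplyr::mutate(target_id = "t", count = rep(1:20, each = 2))
  counts$count[counts$day == 9] <- counts$count[counts$day == 9] * 3L
  norm <- normalize_counts(counts)
  expect_equal(norm$cpm[norm$day == 0], norm$cpm[norm$day == 9])
  sums <- dplyr::count(norm, day, wt = cpm)
  expect_equal(sums$n, c(1e6, 1e6))
  bad <- dplyr::mutate(counts, count = ifelse(day == 9, 0L, count))
  expect_error(normalize_counts(bad), "all-zero sample")
})

test_that("gRNA LFC is zero against itself and matches the growth model", {
  sim <- simulate_screen_counts(null_screen_config(3))
  norm <- normalize_counts(sim$counts)
  self <- grna_lfc(norm, day = 0)
  expect_true(all(self$lfc == 0))
  expect_error(grna_lfc(norm, day = 4), "absent")

  # one depleted target among many nulls: closed-form expectation
  tg <- dplyr::bind_rows(
    tibble::tibble(target_id = "dep", n_grnas = 6L, fitness = -0.3),
    tibble::tibble(target_id = sprintf("N%03d", 1:100), n_grnas = 3L,
                   fitness = 0))
  sim2 <- simulate_screen_counts(sim_screen_config(tg, depth = 1e6,
                                                   seed = 4))
  lfc <- grna_lfc(normalize_counts(sim2$counts), day = 9)
  dep <- lfc$lfc[lfc$target_id == "dep"]
  # 9 days x 1 doubling/day at (1+s) = 0.7; composition shift is tiny here
  expect_equal(mean(dep), 9 * log2(0.7), tolerance = 0.05)
  nt <- lfc$lfc[lfc$target_id == "nontargeting"]
  expect_lt(abs(median(nt)), 0.1)
})

test_that("replicate correlation: identity, null, and shared-effect regimes", {
  sim <- simulate_screen_counts(null_screen_config(5, n_targets = 120,
                                                   depth = 1e6))
  lfc <- grna_lfc(normalize_counts(sim$counts), day = 9)
  a <- dplyr::filter(lfc, replicate == 1)
  b <- dplyr::filter(lfc, replicate == 2)
  expect_equal(replicate_correlation(a, a)$r, 1)
  expect_lt(abs(replicate_correlation(a, b)$r), 0.1)  # pure noise

  # 20% of targets carry real effects shared by replicates
  tg <- tibble::tibble(target_id = sprintf("T%03d", 1:100), n_grnas = 3L,
                       fitness = c(rep(-0.25, 10), rep(0.2, 10),
                                   rep(0, 80)))
  sim2 <- simulate_screen_counts(sim_screen_config(tg, depth = 1e6,
                                                   seed = 6))
  lfc2 <- grna_lfc(normalize_counts(sim2$counts), day = 9)
  r <- replicate_correlation(dplyr::filter(lfc2, replicate == 1),
                             dplyr::filter(lfc2, replicate == 2))$r
  expect_gte(r, 0.7)
  expect_error(replicate_correlation(a[1:5, ], b[1:5, ]), ">= 10")
})

test_that("target aggregation calls injected depleted targets and respects bounds", {
  tg <- dplyr::bind_rows(
    tibble::tibble(target_id = sprintf("dep%d", 1:3), n_grnas = 3L,
                   fitness = -0.3),
    tibble::tibble(target_id = sprintf("N%03d", 1:200), n_grnas = 3L,
                   fitness = 0))
  sim <- simulate_screen_counts(sim_screen_config(tg, seed = 7))
  lfc <- grna_lfc(normalize_counts(sim$counts), day = 9)
  sel <- aggregate_targets(lfc, n_perm = 1000, seed = 8)
  dep <- sel[grepl("^dep", sel$target_id), ]
  expect_true(all(dep$direction == "negative"))
  expect_true(all(dep$fdr_depleted <= 0.8))
  # permutation p never 0, floored at 1/(n_perm + 1)
  tested <- sel$status == "tested"
  expect_true(all(sel$p_depleted[tested] >= 1 / 1001))
  expect_true(all(sel$p_enriched[tested] >= 1 / 1001))
  # nontargeting is pooled but never called
  expect_equal(sel$status[sel$target_id == "nontargeting"], "control")
  # bit-exact reproducibility of the permutation scheme
  sel2 <- aggregate_targets(lfc, n_perm = 1000, seed = 8)
  expect_identical(sel, sel2)
  expect_false(identical(
    sel$p_depleted,
    aggregate_targets(lfc, n_perm = 1000, seed = 9)$p_depleted))
})

test_that("single-gRNA targets are reported untested", {
  lfc <- tibble::tibble(
    grna_id = c("a1", "a2", "b1", sprintf("n%d", 1:10)),
    target_id = c("A", "A", "B", rep("nontargeting", 10)),
    replicate = 1L, day = 9,
    lfc = rnorm(13))
  sel <- aggregate_targets(lfc, n_perm = 1000, seed = 1)
  expect_equal(sel$status[sel$target_id == "B"], "untested")
  expect_equal(sel$direction[sel$target_id == "B"], "none")
  expect_equal(sel$status[sel$target_id == "A"], "tested")
})

test_that("stronger depletion gives stochastically lower aggregated LFC", {
  tg <- dplyr::bind_rows(
    tibble::tibble(target_id = sprintf("s%d", 1:4), n_grnas = 4L,
                   fitness = c(-0.05, -0.15, -0.25, -0.35)),
    tibble::tibble(target_id = sprintf("N%02d", 1:50), n_grnas = 3L,
                   fitness = 0))
  sim <- simulate_screen_counts(sim_screen_config(tg, depth = 1e6,
                                                  seed = 10))
  lfc <- grna_lfc(normalize_counts(sim$counts), day = 9)
  sel <- aggregate_targets(lfc, n_perm = 1000, seed = 2)
  ord <- sel$median_lfc[match(sprintf("s%d", 1:4), sel$target_id)]
  expect_true(all(diff(ord) < 0))  # s grid -0.05 .. -0.35
})
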