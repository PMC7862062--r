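# shared fixture: a small long-format Psi table with 12 sites x 5 pairs
make_psi_fixture <- function(seed = 1, shift = 0, sd = 0.03,
                             n_sites = 12, n_pairs = 5, base = 0.4) {
  set.seed(seed)
  sites <- sprintf("M:%d", seq(10, by = 10, length.out = n_sites))
  units <- sprintf("P%d", seq_len(n_pairs))
  grid <- expand.grid(site_id = sites, unit = units,
                      cond = c("T", "N"), stringsAsFactors = FALSE)
  grid$position <- as.integer(sub("M:", "", grid$site_id))
  grid$molecule <- "M"
  grid$psi_ratio <- pmin(1, pmax(0, base + rnorm(nrow(grid), 0, sd) +
                                   ifelse(grid$cond == "T", shift, 0)))
  grid$sample_id <- paste0(grid$unit, "_", grid$cond)
  tibble::as_tibble(grid[c("site_id", "molecule", "position",
                           "psi_ratio", "sample_id")])
}

make_design <- function(n_pairs = 5) {
  units <- sprintf("P%d", seq_len(n_pairs))
  tibble::tibble(unit = units, sample_a = paste0(units, "_T"),
                 sample_b = paste0(units, "_N"))
}

test_that("identical conditions give zero delta and degenerate p = 1", {
  psi <- make_psi_fixture()
  units <- sprintf("P%d", 1:5)
  design <- tibble::tibble(unit = units,
                           sample_a = paste0(units, "_T"),
                           sample_b = paste0(units, "_T"))
  st <- site_tests(psi, design)
  expect_true(all(st$delta == 0))
  expect_true(all(st$p == 1))
  expect_true(all(st$degenerate))
  expect_false(any(st$significant))
})

test_that("swapping condition labels negates effect sizes and keeps p", {
  psi <- make_psi_fixture(shift = 0.1)
  design <- make_design()
  flipped <- dplyr::rename(design, sample_a = sample_b,
                           sample_b = sample_a)
  st1 <- site_tests(psi, design)
  st2 <- site_tests(psi, flipped)
  expect_equal(st1$delta, -st2$delta)
  expect_equal(st1$p, st2$p)
  # log FC of means is antisymmetric up to the shared pseudocount
  expect_equal(st1$lfc, -st2$lfc, tolerance = 1e-12)
})

test_that("a consistent shift is detected per site at n = 5 pairs", {
  st <- site_tests(make_psi_fixture(seed = 7, shift = 0.15), make_design())
  expect_true(all(st$significant))
  expect_true(all(st$delta > 0.1))
  expect_true(all(st$q <= st$p | st$q >= st$p))  # q defined everywhere
  expect_true(all(!is.na(st$q)))
})

test_that("sites with too few complete pairs are reported untested", {
  psi <- make_psi_fixture()
  psi$psi_ratio[psi$site_id == "M:10" &
                  psi$sample_id %in% c("P1_T", "P2_T", "P3_T")] <- NA
  st <- site_tests(psi, make_design())
  expect_equal(st$status[st$site_id == "M:10"], "untested")
  expect_true(is.na(st$p[st$site_id == "M:10"]))
  expect_true(all(st$status[st$site_id != "M:10"] == "tested"))
})

test_that("global shift test: null gives p = 1, saturated shift the exact floor", {
  psi <- make_psi_fixture(n_sites = 10)
  same <- global_shift_test(psi, "P1_T", "P1_T")
  expect_equal(same$p.value, 1)

  shifted <- dplyr::mutate(psi, psi_ratio = ifelse(grepl("_T$", sample_id),
                                                   psi_ratio + 0.2,
                                                   psi_ratio))
  gt <- global_shift_test(shifted, "P1_T", "P1_N")
  # all 10 paired differences one-signed: exact two-sided floor 2 / 2^10
  expect_equal(gt$p.value, 2 / 2^10)
  expect_error(global_shift_test(psi[psi$site_id %in% c("M:10", "M:20"), ],
                                 "P1_T", "P1_N"),
               "need >= 6")
})

test_that("restricting the global test to all sites equals no restriction", {
  psi <- make_psi_fixture(shift = 0.05, seed = 3)
  all_ids <- unique(psi$site_id)
  t_all <- global_shift_test(psi, make_design()$sample_a,
                             make_design()$sample_b)
  t_subset <- global_shift_test(psi, make_design()$sample_a,
                                make_design()$sample_b, sites = all_ids)
  expect_equal(t_all$p.value, t_subset$p.value)
  expect_equal(t_all$n, t_subset$n)
})

test_that("a single-site hotspot reduces to the per-site paired t", {
  psi <- make_psi_fixture(shift = 0.12, seed = 5)
  design <- make_design()
  ht <- hotspot_test(psi, design, "M", 30)
  st <- site_tests(psi, design)
  row <- st[st$site_id == "M:30", ]
  expect_equal(ht$p.value, row$p)
  expect_equal(ht$estimate, row$delta)
})

test_that("hotspot test on the three-site fixture region detects a coordinated shift", {
  psi <- make_psi_fixture(shift = 0.05, sd = 0.02, seed = 11)
  ht <- hotspot_test(psi, make_design(), "M", c(10, 20, 30))
  expect_lt(ht$p.value, 0.05)
  g <- glance(ht)
  expect_gt(g$mean_sum_a, g$mean_sum_b)
  # fewer than 3 complete pairs -> untested
  psi$psi_ratio[psi$sample_id %in% c("P1_T", "P2_T", "P3_T") &
                  psi$position == 20] <- NA
  ht2 <- hotspot_test(psi, make_design(), "M", c(10, 20, 30))
  expect_equal(ht2$status, "untested")
  expect_true(is.na(ht2$p.value))
})

test_that("tidy and glance return one-row summaries", {
  psi <- make_psi_fixture(shift = 0.1)
  ht <- hotspot_test(psi, make_design(), "M", c(10, 20))
  expect_s3_class(tidy(ht), "tbl_df")
  expect_equal(nrow(tidy(ht)), 1)
  expect_true(all(c("mean_sum_a", "mean_sum_b") %in% names(glance(ht))))
})
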