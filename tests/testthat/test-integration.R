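volcano_fixture <- function() {
  tibble::tibble(
    snorna_id = c("SNORA65", "SNORA7A", "SNORA7B", "SNORA-x", "SNORA-y"),
    class = "HACA_box",
    lfc = c(2.4, 1.9, 2.1, 0.1, -0.3),
    p = c(0.01, 0.03, 0.02, 0.8, 0.6),
    flag = c("enriched", "enriched", "enriched", "none", "none"))
}

sites_fixture <- function() {
  tibble::tibble(
    site_id = c("28S:4417", "28S:1771", "18S:105", "18S:200"),
    molecule = c("28S", "28S", "18S", "18S"),
    position = c(4417L, 1771L, 105L, 200L),
    delta = c(0.12, 0.08, 0.1, -0.02),
    lfc = c(0.4, 0.3, 0.35, -0.05),
    p = c(0.01, 0.04, 0.02, 0.7),
    significant = c(TRUE, TRUE, TRUE, FALSE))
}

map_fixture <- function() {
  tibble::tibble(
    snorna_id = c("SNORA65", "SNORA7A", "SNORA7B", "SNORA-x"),
    molecule = c("28S", "28S", "28S", "18S"),
    position = c(4417L, 1771L, 1771L, 200L))
}

test_that("vectorized Fisher p matches stats::fisher.test across random tables", {
  set.seed(19)
  tabs <- matrix(rpois(4 * 150, 6), ncol = 4)
  ours <- fisher_exact_p(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
  ref <- apply(tabs, 1, function(x) {
    fisher.test(matrix(x, 2, byrow = TRUE))$p.value
  })
  expect_equal(ours, ref, tolerance = 1e-12)
  # the worked 2x2 example: strong concordance
  expect_equal(fisher_exact_p(9, 1, 10, 90),
               fisher.test(matrix(c(9, 1, 10, 90), 2, byrow = TRUE))$p.value)
})

test_that("join links guides to their target sites and conserves rows", {
  linked <- join_results(volcano_fixture(), sites_fixture(), map_fixture())
  lk <- linked[linked$link == "linked", ]
  expect_equal(nrow(lk), nrow(map_fixture()))  # sum of per-guide targets
  # the single-guide fixture: SNORA65 joined to 28S:4417
  row <- lk[lk$snorna_id == "SNORA65", ]
  expect_equal(row$site_id, "28S:4417")
  expect_equal(row$de_flag, "enriched")
  expect_equal(row$psi_delta, 0.12)
  # the shared site carries both of its guides
  expect_setequal(lk$snorna_id[lk$site_id == "28S:1771"],
                  c("SNORA7A", "SNORA7B"))
  # pass-throughs flagged, not dropped
  expect_equal(linked$link[linked$snorna_id %in% "SNORA-y"],
               "unmapped_snorna")
  expect_equal(linked$link[linked$site_id %in% "18S:105"],
               "unmapped_site")
})

test_that("an empty map yields no linked rows, everything flagged", {
  empty <- map_fixture()[0, ]
  linked <- join_results(volcano_fixture(), sites_fixture(), empty)
  expect_equal(sum(linked$link == "linked"), 0)
  expect_equal(sum(linked$link == "unmapped_snorna"),
               nrow(volcano_fixture()))
  expect_equal(sum(linked$link == "unmapped_site"), nrow(sites_fixture()))
})

test_that("a map pointing at unknown sites errors listing the offenders", {
  bad <- dplyr::bind_rows(map_fixture(),
                          tibble::tibble(snorna_id = "SNORA-z",
                                         molecule = "28S",
                                         position = 9999L))
  expect_error(join_results(volcano_fixture(), sites_fixture(), bad),
               "28S:9999")
})

make_linked <- function(m, hyper, up, seed = NULL) {
  # m sites, one guide each; hyper/up are logical vectors of length m
  tibble::tibble(
    snorna_id = sprintf("G%03d", seq_len(m)),
    site_id = sprintf("S%03d", seq_len(m)),
    de_flag = ifelse(up, "enriched", "none"),
    psi_p = ifelse(hyper, 0.01, 0.5),
    psi_delta = ifelse(hyper, 0.1, 0.0),
    link = "linked")
}

test_that("concordance detects co-occurring enrichment and hyper-Psi", {
  m <- 40
  up <- c(rep(TRUE, 12), rep(FALSE, 28))
  hyper <- c(rep(TRUE, 10), rep(FALSE, 30))  # 10 of the 12 up sites
  ct <- concordance_test(make_linked(m, hyper, up))
  expect_lt(ct$p.value, 0.001)
  g <- glance(ct)
  expect_equal(g$n_hyper_up, 10)
  expect_equal(g$n_hyper_up + g$n_hyper_notup + g$n_nothyper_up +
                 g$n_nothyper_notup, m)
  # permutation mode agrees with the hypergeometric upper tail to
  # Monte-Carlo accuracy (moderate-overlap table so p is estimable)
  hyper2 <- seq_len(m) %in% c(1:6, 13:16)
  cp <- concordance_test(make_linked(m, hyper2, up), mode = "permutation",
                         n_perm = 20000, seed = 3)
  oracle_tail <- sum(dhyper(6:10, 10, 30, 12))
  expect_equal(cp$p.value, oracle_tail, tolerance = 0.25)
})

test_that("degenerate margins report p = 1 with a flag", {
  m <- 12
  ct <- concordance_test(make_linked(m, hyper = rep(TRUE, m),
                                     up = c(rep(TRUE, 4), rep(FALSE, 8))))
  expect_equal(ct$p.value, 1)
  expect_equal(ct$status, "degenerate_margin")
})

test_that("type-I error of the concordance test is controlled under independence", {
  set.seed(23)
  p_values <- replicate(150, {
    m <- 40
    concordance_test(make_linked(m, hyper = runif(m) < 0.3,
                                 up = runif(m) < 0.4))$p.value
  })
  expect_lte(mean(p_values < 0.05), 0.07)  # exact test is conservative
  expect_gt(mean(p_values > 0.5), 0.3)
})

test_that("too few linked sites is an error", {
  expect_error(concordance_test(make_linked(5, rep(TRUE, 5), rep(FALSE, 5))),
               "need >= 10")
})
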