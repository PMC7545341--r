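make_site_row <- function(mir, target, cls, S, dG) {
  data.frame(mirna = mir, target = target, target_class = cls,
             start = 10L, end = 18L, seed_class = "8mer", S = S, dG = dG,
             detected_by = "seed+alignment", stringsAsFactors = FALSE)
}

test_that("shared_mre_triples enumerates the cross product per miRNA", {
  st <- rbind(make_site_row("mirX", "lnc1", "lncRNA", 100, -20),
              make_site_row("mirX", "lnc2", "lncRNA", 90, -18),
              make_site_row("mirX", "m1", "mRNA-3'UTR", 60, -9),
              make_site_row("mirX", "m2", "mRNA-3'UTR", 60, -9),
              make_site_row("mirX", "m3", "mRNA-3'UTR", 60, -9),
              make_site_row("mirY", "lnc9", "lncRNA", 80, -15))
  tr <- shared_mre_triples(st)
  # one miRNA hitting 2 lncRNAs and 3 mRNAs yields 6 triples
  expect_equal(nrow(tr), 6)
  expect_true(all(tr$mir == "mirX"))
  expect_setequal(unique(tr$lnc), c("lnc1", "lnc2"))
  # mirY has no mRNA site, so it forms no triple
  expect_false("lnc9" %in% tr$lnc)
  expect_equal(nrow(shared_mre_triples(st[0, ])), 0)
})

make_screen_fixture <- function(n = 20, seed = 1) {
  set.seed(seed)
  s <- paste0("s", seq_len(n))
  z <- rnorm(n)
  expr <- list(
    lncRNA = rbind(lnc1 = 8 + z + rnorm(n, sd = 0.01),
                   lnc2 = rnorm(n, 8)),
    miRNA = rbind(mirX = 6 - z + rnorm(n, sd = 0.01),
                  mirY = rnorm(n, 6)),
    mRNA = rbind(m1 = 9 + z + rnorm(n, sd = 0.01),
                 m2 = rnorm(n, 9)))
  for (cls in names(expr)) colnames(expr[[cls]]) <- s
  expr
}

test_that("anticorrelation criterion is signed, not absolute", {
  expr <- make_screen_fixture()
  ac <- anticorrelation_criterion(expr, c(lnc = "lnc1", mir = "mirX",
                                          mrna = "m1"), cutoff_neg = 0.9)
  expect_true(ac$ok)
  expect_lt(ac$r_mir_lnc, -0.9)
  expect_lt(ac$r_mir_mrna, -0.9)
  expect_gt(ac$r_lnc_mrna, 0.9)
  # a strong POSITIVE correlation with the miRNA must fail: swap the miRNA
  # for a positively co-varying feature
  expr2 <- expr
  expr2$miRNA["mirX", ] <- expr$lncRNA["lnc1", ] + rnorm(20, sd = 0.01)
  ac2 <- anticorrelation_criterion(expr2, c(lnc = "lnc1", mir = "mirX",
                                            mrna = "m1"), cutoff_neg = 0.9)
  expect_false(ac2$ok)
  expect_gt(ac2$r_mir_lnc, 0.9)
})

test_that("competition criterion requires strict dominance on both axes", {
  a <- list(S = 100, dG = -20); b <- list(S = 60, dG = -9)
  expect_true(competition_criterion(a, b))
  expect_false(competition_criterion(b, a))
  expect_false(competition_criterion(list(S = 100, dG = -9), b))   # dG ties
  expect_false(competition_criterion(list(S = 60, dG = -20), b))   # S ties
  expect_error(competition_criterion(list(S = NA, dG = -20), b), "finite")
})

test_that("screen_axes nominates only full-conjunction core axes", {
  expr <- make_screen_fixture()
  st <- rbind(make_site_row("mirX", "lnc1", "lncRNA", 100, -20),
              make_site_row("mirX", "lnc2", "lncRNA", 100, -20),
              make_site_row("mirX", "m1", "mRNA-3'UTR", 60, -9),
              make_site_row("mirX", "m2", "mRNA-3'UTR", 60, -9))
  res <- screen_axes(st, expr, core_lnc = "lnc1", core_mrna = "m1",
                     anticorr_cutoff = 0.9)
  expect_equal(nrow(res$axes), 4)          # 2 lnc x 1 mir x 2 mrna
  # only lnc1/mirX/m1 is anticorrelated AND both-core
  expect_equal(nrow(res$nominated), 1)
  expect_equal(res$nominated$lnc, "lnc1")
  expect_equal(res$nominated$mrna, "m1")
  with(res$nominated, expect_true(all(crit_shared & crit_anticorr &
                                        crit_competition & lnc_is_core &
                                        mrna_is_core)))
  # candidates satisfy criteria 1-3 regardless of core membership
  expect_true(all(res$candidates$crit_anticorr &
                    res$candidates$crit_competition))
  # decoy triples are audited but not retained
  expect_false("lnc2" %in% res$candidates$lnc)
  # the nominated axis ranks first in the audit table
  expect_equal(res$axes$lnc[1], "lnc1")
  expect_equal(res$axes$mrna[1], "m1")
})

test_that("screen_axes audit mode keeps all triples as candidates", {
  expr <- make_screen_fixture()
  st <- rbind(make_site_row("mirX", "lnc1", "lncRNA", 100, -20),
              make_site_row("mirX", "lnc2", "lncRNA", 100, -20),
              make_site_row("mirX", "m1", "mRNA-3'UTR", 60, -9))
  strict <- screen_axes(st, expr, core_lnc = "lnc1", core_mrna = "m1",
                        anticorr_cutoff = 0.9)
  audit <- screen_axes(st, expr, core_lnc = "lnc1", core_mrna = "m1",
                       anticorr_cutoff = 0.9, apply_filters = FALSE)
  expect_equal(nrow(audit$candidates), nrow(audit$axes))
  expect_equal(audit$nominated, strict$nominated)
})

test_that("a failed competition criterion blocks nomination", {
  expr <- make_screen_fixture()
  # the lncRNA site is WEAKER than the mRNA site
  st <- rbind(make_site_row("mirX", "lnc1", "lncRNA", 60, -9),
              make_site_row("mirX", "m1", "mRNA-3'UTR", 100, -20))
  expect_warning(
    screen_axes(st, expr, core_lnc = "lnc1", core_mrna = "m1",
                anticorr_cutoff = 0.9),
    "no axis passed")
  res <- suppressWarnings(
    screen_axes(st, expr, core_lnc = "lnc1", core_mrna = "m1",
                anticorr_cutoff = 0.9))
  expect_equal(nrow(res$candidates), 0)
  expect_equal(nrow(res$nominated), 0)
  expect_false(res$axes$crit_competition[1])
})

test_that("an empty site table yields an empty screen with a warning", {
  expr <- make_screen_fixture()
  st <- make_site_row("mirX", "lnc1", "lncRNA", 100, -20)[0, ]
  expect_warning(res <- screen_axes(st, expr), "no shared-MRE triples")
  expect_equal(nrow(res$axes), 0)
  expect_equal(nrow(res$nominated), 0)
})

test_that("centrality-aware ranking prefers high differential hubs", {
  expr <- make_screen_fixture()
  # make lnc2/m2 anticorrelated with mirX too, so two axes pass criteria 1-3
  expr$lncRNA["lnc2", ] <- -expr$miRNA["mirX", ] + 14 + rnorm(20, sd = 0.01)
  expr$mRNA["m2", ] <- -expr$miRNA["mirX", ] + 15 + rnorm(20, sd = 0.01)
  st <- rbind(make_site_row("mirX", "lnc1", "lncRNA", 100, -20),
              make_site_row("mirX", "lnc2", "lncRNA", 100, -20),
              make_site_row("mirX", "m1", "mRNA-3'UTR", 60, -9),
              make_site_row("mirX", "m2", "mRNA-3'UTR", 60, -9))
  centrality <- data.frame(id = c("lnc1", "lnc2", "m1", "m2"),
                           delta_rd = c(0.1, 1.0, 0.1, 0.9))
  res <- screen_axes(st, expr, core_lnc = c("lnc1", "lnc2"),
                     core_mrna = c("m1", "m2"), anticorr_cutoff = 0.9,
                     centrality = centrality)
  expect_gte(nrow(res$nominated), 2)
  expect_equal(res$nominated$lnc[1], "lnc2")
  expect_equal(res$nominated$mrna[1], "m2")
  expect_equal(res$nominated$delta_rd_sum[1], 1.9)
})
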