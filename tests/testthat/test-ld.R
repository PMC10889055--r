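test_that("r-squared is 1 for identical columns and matches a toy count", {
  hap <- haplotype_matrix(cbind(a = c(1, 1, 0, 0, 1, 0, 0, 1),
                                b = c(1, 1, 0, 0, 1, 0, 0, 1),
                                c = c(1, 0, 1, 0, 1, 0, 1, 0)))
  expect_equal(r_squared(hap, "a", "b"), 1)
  # brute-force haplotype-class counting on the 8-row toy matrix
  expect_equal(r_squared(hap, "a", "c"),
               r2_brute(hap$haplotypes[, "a"], hap$haplotypes[, "c"]))
})

test_that("r-squared equals brute-force counting and squared correlation", {
  set.seed(8)
  for (rep in 1:200) {
    n <- sample(4:16, 1)
    repeat {
      x <- rbinom(n, 1, 0.5)
      y <- if (runif(1) < 0.5) x else rbinom(n, 1, 0.5)
      if (runif(1) < 0.3) y <- 1 - x
      if (var(x) > 0 && var(y) > 0) break
    }
    hap <- haplotype_matrix(cbind(a = x, b = y))
    r2 <- r_squared(hap, "a", "b")
    expect_equal(r2, r2_brute(x, y))
    expect_equal(r2, cor(x, y)^2)
    # symmetry and invariance to relabelling 0 <-> 1
    expect_equal(r_squared(hap, "b", "a"), r2)
    flip <- haplotype_matrix(cbind(a = 1 - x, b = y))
    expect_equal(r_squared(flip, "a", "b"), r2)
  }
})

test_that("independent columns decorrelate at large haplotype counts", {
  set.seed(5)
  hap <- haplotype_matrix(cbind(a = rbinom(10000, 1, 0.3),
                                b = rbinom(10000, 1, 0.4)))
  expect_lt(r_squared(hap, "a", "b"), 0.01)
})

test_that("monomorphic variants give an explicit undefined-LD error", {
  hap <- haplotype_matrix(cbind(a = c(1, 0, 1, 0), b = c(0, 0, 0, 0)))
  expect_error(r_squared(hap, "a", "b"), "monomorphic.*b")
})

test_that("correlated groups collect variants above the r2 threshold", {
  set.seed(12)
  n <- 2000
  anchor <- rbinom(n, 1, 0.3)
  mk <- function(p_copy) ifelse(runif(n) < p_copy, anchor, rbinom(n, 1, 0.3))
  hap <- haplotype_matrix(cbind(anchor = anchor, tight = mk(0.99),
                                close = mk(0.95), loose = mk(0.5),
                                free = rbinom(n, 1, 0.3)))
  r2 <- vapply(c("tight", "close", "loose", "free"),
               function(id) r_squared(hap, "anchor", id), 0)
  grp <- correlated_group(hap, "anchor", threshold = 0.8)
  expect_setequal(grp$member_ids,
                  c("anchor", names(r2)[r2 >= 0.8]))
  expect_equal(grp$r2_to_anchor[["anchor"]], 1)
  # a threshold just above every off-anchor r2 leaves a singleton
  solo <- correlated_group(hap, "anchor",
                           threshold = max(r2) + 1e-9)
  expect_identical(solo$member_ids, "anchor")
  # identical columns survive any threshold <= 1
  hap2 <- haplotype_matrix(cbind(anchor = anchor, twin = anchor,
                                 free = rbinom(n, 1, 0.3)))
  expect_setequal(correlated_group(hap2, "anchor", 1)$member_ids,
                  c("anchor", "twin"))
})

test_that("monomorphic variants are excluded from grouping with a warning", {
  hap <- haplotype_matrix(cbind(a = c(1, 0, 1, 0), b = c(1, 0, 1, 0),
                                mono = c(1, 1, 1, 1)))
  expect_warning(grp <- correlated_group(hap, "a"), "mono")
  expect_setequal(grp$member_ids, c("a", "b"))
})

test_that("group contrasts expose divergent effects among linked variants", {
  nc <- data.frame(
    variant_id = rep(c("anchor", "twin"), each = 2),
    feature = rep(c("F1", "F2"), 2),
    log_odds_change = c(2.4, 0, 0, 0),
    stringsAsFactors = FALSE)
  grp <- structure(list(anchor_id = "anchor",
                        member_ids = c("anchor", "twin"),
                        r2_to_anchor = c(anchor = 1, twin = 0.98),
                        threshold = 0.8),
                   class = "ld_group")
  res <- compare_group_effects(grp, nc)
  expect_equal(res$divergence$divergence[res$divergence$feature == "F1"], 2.4)
  expect_equal(res$divergence$divergence[res$divergence$feature == "F2"], 0)
  expect_equal(nrow(res$flagged), 1)
  expect_equal(res$flagged$variant_id, "twin")
  expect_equal(res$flagged$feature, "F1")
  expect_equal(res$flagged$anchor_log_odds_change, 2.4)
  # a group with no effects anywhere has zero divergence everywhere
  none <- nc
  none$log_odds_change <- 0
  expect_true(all(compare_group_effects(grp, none)$divergence$divergence == 0))
  # missing member records are reported
  expect_error(compare_group_effects(grp, nc[nc$variant_id == "anchor", ]),
               "twin")
})
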