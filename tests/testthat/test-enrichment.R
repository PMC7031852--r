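test_that("hypergeometric upper tail matches enumeration exactly", {
  expect_equal(hypergeomUpper(0, 5, 3, 20), 1)
  expect_equal(hypergeomUpper(1, 1, 1, 2), 0.5)
  # every consistent table with background <= 12
  for (N in 2:12) for (K in 1:(N - 1)) for (n in 1:(N - 1)) {
    for (a in max(0, K + n - N):min(K, n)) {
      expect_equal(hypergeomUpper(a, K, n, N), bruteHyperUpper(a, K, n, N),
                   tolerance = 1e-12)
    }
  }
  expect_error(hypergeomUpper(5, 3, 3, 10), "exceeds")
  expect_error(hypergeomUpper(1, 15, 3, 10), "inconsistent")
})

test_that("Fisher one-sided p equals the hypergeometric tail (identity)", {
  ft <- fisherExact2x2(2, 2, 2, 2)
  expect_equal(ft$odds_ratio, 1)
  expect_equal(ft$p_two_sided, 1)
  expect_equal(fisherExact2x2(1, 0, 0, 1)$p_greater, 0.5)
  for (N in 2:12) {
    for (a in 0:N) for (b in 0:(N - a)) for (cc in 0:(N - a - b)) {
      d <- N - a - b - cc
      if (a + b == 0 || a + cc == 0) next
      got <- fisherExact2x2(a, b, cc, d)
      expect_equal(got$p_greater,
                   hypergeomUpper(a, a + cc, a + b, N), tolerance = 1e-12)
    }
  }
  expect_error(fisherExact2x2(0, 0, 3, 4), "degenerate")
})

test_that("Fisher p-values agree with the reference implementation", {
  set.seed(4)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 8), 2)
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
    if (a + b == 0 || a + cc == 0) next
    got <- fisherExact2x2(a, b, cc, d)
    expect_equal(got$p_two_sided,
                 fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(got$p_greater,
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment implements the step-up definition", {
  expect_equal(bhAdjust(0.037), 0.037)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")

  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, p.adjust(p, "BH")) # independent reference
    expect_true(all(adj >= p - 1e-15))
    # re-adjusting can only move values up, never down, and never past 1
    re <- bhAdjust(adj)
    expect_true(all(re >= adj - 1e-15) && all(re <= 1))
    perm <- sample(length(p))
    expect_equal(bhAdjust(p[perm]), adj[perm]) # permutation invariance
  }
})

test_that("gene-list enrichment builds the table by set algebra", {
  r <- enrichGeneLists("g1", "g1", c("g1", "g2"))
  expect_equal(unlist(r[c("a", "b", "c", "d")]),
               c(a = 1, b = 0, c = 0, d = 1))
  expect_equal(r$p_greater, 0.5)

  expect_error(enrichGeneLists("g1", "g9", c("g1", "g2")), "degenerate")
  expect_error(enrichGeneLists(c("g1", "gX"), "g1", c("g1", "g2")),
               "subset")

  # genes outside the background never count
  r2 <- enrichGeneLists(c("g1", "g2"), c("g1", "offBg"),
                        c("g1", "g2", "g3", "g4"))
  expect_equal(r2$set_size_used, 1)

  # growing the background strictly sharpens a fixed positive overlap
  ps <- vapply(c(10, 20, 40, 80), function(N)
    enrichGeneLists(paste0("g", 1:5), paste0("g", c(1:3, 9)),
                    paste0("g", 1:N))$p_greater, 1)
  expect_true(all(diff(ps) < 0))
})

test_that("multi-set enrichment reports BH-adjusted one-sided p-values", {
  bg <- paste0("g", 1:60)
  de <- bg[1:12]
  sets <- list(hit = bg[1:10], miss = bg[40:50], part = bg[c(5:8, 30:38)])
  tb <- enrichTable(de, sets, bg)
  expect_equal(nrow(tb), 3L)
  expect_equal(tb$p_BH, bhAdjust(tb$p_greater))
  expect_true(all(tb$p_BH >= tb$p_greater - 1e-15))
  expect_lt(tb$p_greater[tb$set == "hit"], 0.001)
})
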