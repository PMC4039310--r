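test_that("normalize_screen divides by the control mean and is idempotent", {
  scr <- make_screen(list(L1 = list(g1 = c(2000, 2200))),
                     list(L1 = c(2000, 2000)))
  ns <- normalize_screen(scr)
  expect_equal(ns$readings$readout[!ns$readings$is_control], c(1.0, 1.1))
  expect_equal(mean(ns$readings$readout[ns$readings$is_control]), 1)
  expect_equal(normalize_screen(ns)$readings, ns$readings)
  # zero control mean errors naming the line
  bad <- make_screen(list(L9 = list(g1 = c(1, 2))), list(L9 = c(0, 0)))
  expect_error(normalize_screen(bad), "L9")
})

test_that("call_hits applies the >50% inhibition AND p<0.05 conjunction", {
  scr <- make_screen(
    list(L1 = list(hit = c(800, 900, 840),      # ~0.42 viability
                   weak = c(1200, 1100, 1160),  # inhibition < 0.5
                   flat = c(2000, 2040, 1960))),
    list(L1 = c(2000, 2040, 1960)))
  hits <- call_hits(normalize_screen(scr))
  h <- hits[hits$gene == "hit", ]
  expect_equal(h$inhibition, 1 - mean(c(800, 900, 840)) / 2000)
  expect_gt(h$inhibition, 0.5)
  # oracle: equal-variance two-sample t against the normalized controls
  x <- c(800, 900, 840) / 2000; y <- c(2000, 2040, 1960) / 2000
  sp <- sqrt((2 * var(x) + 2 * var(y)) / 4)
  tstat <- (mean(x) - mean(y)) / (sp * sqrt(2 / 3))
  expect_equal(h$p_value, 2 * pt(-abs(tstat), df = 4))
  expect_true(h$is_hit)
  # below the inhibition threshold: not a hit regardless of p
  w <- hits[hits$gene == "weak", ]
  expect_lt(w$inhibition, 0.5)
  expect_false(w$is_hit)
  # gene identical to control distribution: p in the 1 region, no hit
  expect_false(hits$is_hit[hits$gene == "flat"])
  expect_gt(hits$p_value[hits$gene == "flat"], 0.9)
})

test_that("hit calling is monotone in viability", {
  base <- c(0.55, 0.6, 0.5)
  ctrl <- c(1.0, 1.02, 0.98)
  for (f in c(1, 0.9, 0.7, 0.5, 0.3)) {
    scr <- make_screen(list(L1 = list(g = 2000 * base * f)),
                       list(L1 = 2000 * ctrl))
    h <- call_hits(normalize_screen(scr))
    if (f <= 0.9) expect_true(h$is_hit) else expect_false(h$is_hit)
  }
})

test_that("core_network and pair_overlap are exact set operations", {
  sets <- list(c("g1", "g2", "g3"), c("g2", "g3", "g4"), c("g2", "g3"))
  expect_equal(core_network(sets), c("g2", "g3"))
  expect_equal(core_network(list(character(), c("g1"))), character())
  expect_error(core_network(list(c("g1"))), "2 cell lines")
  # core is a subset of every per-line hit set
  for (s in sets) expect_true(all(core_network(sets) %in% s))

  ov <- pair_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov, list(shared = c("b", "c"), parent_only = "a",
                        resistant_only = "d"))
  # the three sets partition the union
  expect_length(intersect(ov$shared, ov$parent_only), 0)
  expect_length(intersect(ov$shared, ov$resistant_only), 0)
  expect_setequal(unlist(ov), union(c("a", "b", "c"), c("b", "c", "d")))
  expect_equal(pair_overlap(c("x"), c("x"))$shared, "x")
  expect_length(pair_overlap(c("x"), c("y"))$shared, 0)
})

test_that("resistant_gain requires direction, delta and significance", {
  scr <- make_screen(
    list(P = list(g1 = c(0.9, 0.92, 0.88) * 2000,
                  g2 = c(0.5, 0.52, 0.48) * 2000,
                  g3 = c(0.4, 0.42, 0.41) * 2000),
         R = list(g1 = c(0.4, 0.42, 0.41) * 2000,  # strong gain
                  g2 = c(0.5, 0.52, 0.48) * 2000,  # identical: no gain
                  g3 = c(0.9, 0.92, 0.88) * 2000)),  # higher in resistant
    list(P = rep(2000, 3), R = rep(2000, 3)))
  out <- resistant_gain(normalize_screen(scr), "P", "R", min_delta = 0.2)
  expect_equal(out$gene, "g1")
  expect_lt(out$p_value, 0.05)
})

test_that("ranksum_pvalue matches exact enumeration and handles modes", {
  # worked case: minimum rank-sum, exact two-sided p = 2 / C(5,2) = 0.2
  expect_equal(ranksum_pvalue(c(0.2, 0.3), c(0.8, 0.9, 1.0)), 0.2)
  # identical groups: p in the 1 region
  expect_gte(ranksum_pvalue(c(1, 2, 3), c(1.5, 2.5, 0.5)), 0.5)
  # tied data go through permutation enumeration and stay valid
  p_tied <- ranksum_pvalue(c(1, 1, 2), c(2, 3, 3))
  expect_true(p_tied > 0 && p_tied <= 1)
  expect_equal(p_tied, enum_ranksum_p(c(1, 1, 2), c(2, 3, 3)))
  # large-sample normal mode agrees with the exact mode to first order
  set.seed(1)
  x <- rnorm(11); y <- rnorm(11) + 1.2
  p_norm <- ranksum_pvalue(x, y)          # 11 > exact_max -> normal
  p_exact <- ranksum_pvalue(x, y, exact_max = 11)
  expect_lt(abs(p_norm - p_exact), 0.02)
})

test_that("specificity_test tiers by rank-sum p and absorbs scale", {
  values <- list()
  groups <- c()
  for (i in 1:3) { values[[paste0("M", i)]] <-
    list(g = c(0.2, 0.22, 0.21) * 2000); groups[paste0("M", i)] <- "mutant" }
  for (i in 1:3) { values[[paste0("W", i)]] <-
    list(g = c(0.95, 1.0, 1.05) * 2000); groups[paste0("W", i)] <- "wild-type" }
  ctrl <- setNames(rep(list(rep(2000, 3)), 6), names(values))
  scr <- make_screen(values, ctrl, groups)
  sp <- specificity_test(normalize_screen(scr))
  # complete separation of 3 vs 3: exact p = 2/C(6,3) = 0.1 -> no tier
  expect_equal(sp$p_value, 0.1)
  expect_equal(sp$tier, "")
  expect_true(sp$lower_in_mutant)
  # multiplying one line's raw readings by a constant changes nothing
  scr2 <- scr
  idx <- scr2$readings$cell_line == "M1"
  scr2$readings$readout[idx] <- scr2$readings$readout[idx] * 37
  expect_equal(specificity_test(normalize_screen(scr2)), sp)
  # a group with < 2 lines errors
  scr3 <- make_screen(values[c(1, 4, 5)], ctrl[c(1, 4, 5)],
                      groups[c(1, 4, 5)])
  expect_error(specificity_test(normalize_screen(scr3)), "2 cell lines")
})

test_that("replicate_concordance computes Spearman rho with tie handling", {
  mk <- function(v) make_screen(list(L = as.list(setNames(
    lapply(v, function(x) rep(2000 * x, 2)),
    paste0("g", seq_along(v))))), list(L = rep(2000, 2)))
  expect_equal(replicate_concordance(mk(c(1, 2, 3, 4)), mk(c(1, 2, 3, 4))), 1)
  expect_equal(replicate_concordance(mk(c(1, 2, 3, 4)), mk(c(4, 3, 2, 1))), -1)
  # {1,2,3,4} vs {1,3,2,4}: rho = 1 - 6*2/(4*15) = 0.8
  expect_equal(replicate_concordance(mk(c(1, 2, 3, 4)), mk(c(1, 3, 2, 4))),
               0.8)
  expect_error(replicate_concordance(mk(c(1, 2)), mk(c(1, 2))), "at least 3")
})

test_that("viability_heatmap averages replicates deterministically", {
  scr <- make_screen(list(L1 = list(g1 = c(100, 300), g2 = c(200, 200)),
                          L2 = list(g1 = c(400, 400), g2 = c(100, 100))),
                     list(L1 = c(200, 200), L2 = c(200, 200)))
  m <- viability_heatmap(normalize_screen(scr))
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["g1", "L1"], 1)
  expect_equal(m["g1", "L2"], 2)
  # permuting replicate order leaves the matrix unchanged
  scr2 <- scr
  scr2$readings <- scr2$readings[rev(seq_len(nrow(scr2$readings))), ]
  expect_equal(viability_heatmap(normalize_screen(scr2)), m)
  # row means equal per-gene grand means of the replicate means
  expect_equal(rowMeans(m)[["g2"]], mean(c(1, 0.5)))
})
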