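test_that("hypergeometric upper tail matches enumeration and phyper", {
  # full enumeration for a worked case: C(4,3)C(6,2)+C(4,4)C(6,1) over C(10,5)
  expect_equal(hypergeom_upper_p(10, 5, 4, 3), 66 / 252, tolerance = 1e-14)
  expect_equal(hypergeom_upper_p(10, 5, 4, 0), 1)
  # small-universe agreement with two independent routes (full sweep of the
  # parameter lattice up to L = 12)
  worst_enum <- 0; worst_phyper <- 0
  for (L in 1:12) {
    for (l in seq_len(L)) {
      for (S in seq_len(L)) {
        for (K in 0:min(l, S)) {
          mine <- hypergeom_upper_p(L, l, S, K)
          worst_enum <- max(worst_enum, abs(mine - enum_hyper_upper(L, l, S, K)))
          worst_phyper <- max(worst_phyper,
                              abs(mine - phyper(K - 1, S, L - S, l,
                                                lower.tail = FALSE)))
        }
      }
    }
  }
  expect_lt(worst_enum, 1e-12)
  expect_lt(worst_phyper, 1e-12)
  expect_error(hypergeom_upper_p(10, 12, 4, 3), "bounds")
  expect_error(hypergeom_upper_p(10, 5, 4, 5), "bounds")
})

test_that("extreme tails stay accurate in log space", {
  # binomial coefficients here overflow doubles by hundreds of orders of
  # magnitude; the log-scale accumulation keeps the tail finite and exact
  p <- hypergeom_upper_p(20000, 500, 400, 230)
  expect_gt(p, 0)
  expect_lt(p, 1e-250)
  expect_equal(log(p),
               phyper(229, 400, 19600, 500, lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-10)
})

test_that("CGEA agrees with direct hypergeometric calls on the fixture", {
  fx <- test_fixture()
  gi <- get_set_genes(fx$kb, "KEGG")
  cand <- unique(gi$gene_id)[1:20]
  res <- enrich_test1(fx$kb, cand, "KEGG")
  expect_s3_class(res, "gws_enrich")
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p_e[i],
                 hypergeom_upper_p(res$L[i], res$l[i], res$S[i], res$K[i]))
    expect_equal(res$effect[i], res$K[i] / res$S[i] - res$l[i] / res$L[i])
    expect_equal(res$se[i],
                 sqrt((res$l[i] / res$L[i]) * (1 - res$l[i] / res$L[i]) / res$S[i]))
  }
  # universe is the distinct genes of the category
  expect_equal(res$L[1], length(unique(gi$gene_id)))
  expect_error(enrich_test1(fx$kb, c(-5L, -6L), "KEGG"), "no candidate gene")
})

test_that("a saturated candidate set attains the minimal enumerable p", {
  fx <- test_fixture()
  pid <- set_type_to_pids(fx$kb, "KEGG")[3]
  members <- set_to_genes(fx$kb, pid)
  res <- enrich_test1(fx$kb, members, "KEGG")
  row <- res[res$pid == pid, ]
  expect_equal(row$K, row$S)
  expect_equal(row$effect, 1 - row$l / row$L)
  expect_equal(row$p_e, enum_hyper_upper(row$L, row$l, row$S, row$S),
               tolerance = 1e-12)
  expect_equal(row$pid, res$pid[which.min(res$p_e)])
})

test_that("USGSA counts within the measured universe; alpha = 1 degenerates", {
  fx <- test_fixture()
  g <- uscore(direct_measures(read.delim(fx$files$gwes)))
  res <- enrich_test2(fx$kb, g, alpha = 0.05, category = "KEGG")
  gi <- get_set_genes(fx$kb, "KEGG")
  expect_equal(res$L[1], length(intersect(unique(gi$gene_id), g$gene_id)))
  expect_true(all(res$K <= pmin(res$l, res$S)))
  # the planted set is recovered as the single strongest
  expect_equal(res$pid[1], fx$files$truth$planted[[1]]$pid)
  # degenerate top fraction: everything selected
  d <- enrich_test2(fx$kb, g, alpha = 1, category = "KEGG")
  expect_equal(d$l[1], d$L[1])
  expect_true(all(d$effect <= 0))
  expect_true(all(d$p_e == 1))
})

test_that("type-1 and type-2 tests coincide when selections coincide", {
  fx <- test_fixture()
  g <- uscore(direct_measures(read.delim(fx$files$gwes)))
  res2 <- enrich_test2(fx$kb, g, alpha = 0.05, category = "KEGG")
  selected <- intersect(g$gene_id[g$uscore <= 0.05], attr(res2, "universe"))
  res1 <- enrich_test1(fx$kb, selected, "KEGG")
  cols <- c("pid", "L", "l", "S", "K", "effect", "se", "p_e")
  expect_equal(as.data.frame(res1)[cols], as.data.frame(res2)[cols],
               ignore_attr = TRUE)
})

test_that("permutation adjustment is seeded, monotone and saturates at 1", {
  fx <- test_fixture()
  g <- uscore(direct_measures(read.delim(fx$files$gwes)))
  res <- enrich_test2(fx$kb, g, alpha = 0.05, category = "KEGG")
  a <- perm_adjust(res, B = 100, seed = 5)
  b <- perm_adjust(res, B = 100, seed = 5)
  expect_identical(a$p_perm, b$p_perm)
  expect_identical(a$p_perm_raw, b$p_perm_raw)
  # add-one correction bounds the raw proportion from above
  expect_true(all(a$p_perm >= a$p_perm_raw))
  expect_true(all(a$p_perm <= 1))
  # observed p_e = 1 is never beaten: adjusted p = 1
  expect_equal(a$p_perm_raw[a$p_e == 1], rep(1, sum(a$p_e == 1)))
  # planted set survives adjustment
  expect_equal(a$p_perm_raw[1], 0)
  expect_equal(a$p_perm[1], 1 / 101)
  expect_error(perm_adjust(res, B = 0), "B must be >= 1")
})

test_that("null table reproduces the permutation stream and is monotone", {
  fx <- test_fixture()
  g <- uscore(direct_measures(read.delim(fx$files$gwes)))
  res <- enrich_test2(fx$kb, g, alpha = 0.05, category = "KEGG")
  tab <- build_null_table(res, B = 100, seed = 5)
  pa <- perm_adjust(res, B = 100, seed = 5)
  expect_equal(get_enrich2_p(tab, res$p_e, result = res), pa$p_perm_raw)
  expect_equal(get_enrich2_p(tab, 1.0), 1.0)
  # step function: smaller p_e never yields larger adjusted p
  grid <- sort(runif(50))
  expect_true(all(diff(get_enrich2_p(tab, grid)) >= 0))
  # per-size strata exist and are no less extreme than the overall minimum
  s <- tab$sizes[1]
  expect_true(all(get_enrich2_p(tab, grid, size = s) >=
                  get_enrich2_p(tab, grid)))
  expect_error(get_enrich2_p(tab, 0.5, size = 99999), "stratum")
  # a different universe is refused
  res_go <- enrich_test2(fx$kb, g, alpha = 0.05, category = "GO")
  expect_error(get_enrich2_p(tab, res_go$p_e, result = res_go),
               "fingerprint mismatch")
  # round trip through a file
  f <- tempfile(fileext = ".rds")
  build_null_table(res, B = 100, seed = 5, file = f)
  expect_equal(get_enrich2_p(f, res$p_e), pa$p_perm_raw)
})

test_that("exact p-values are conservative under resampled null candidates", {
  fx <- test_fixture()
  gi <- get_set_genes(fx$kb, "KEGG")
  universe <- unique(gi$gene_id)
  pid <- set_type_to_pids(fx$kb, "KEGG")[2]
  set.seed(31)
  pe <- replicate(200, {
    cand <- sample(universe, 20)
    res <- enrich_test1(fx$kb, cand, "KEGG")
    res$p_e[res$pid == pid]
  })
  # P(p_e <= u) <= u for a valid (conservative) discrete p-value;
  # allow binomial sampling slack
  for (u in c(0.05, 0.2, 0.5))
    expect_lte(mean(pe <= u), u + 2.5 * sqrt(u * (1 - u) / 200))
})

test_that("the top-U-score proportion t-test matches its reference cases", {
  # 20 of 102 genes below 0.05: t = 3.70, p = 1.77e-04
  u <- c(rep(0.01, 20), seq(0.2, 0.9, length.out = 82))
  ht <- uscore_proportion_test(u, 0.05)
  expect_equal(unname(ht$statistic), 3.70, tolerance = 0.002)
  expect_equal(ht$p.value, 1.77e-04, tolerance = 0.005)
  expect_equal(ht$n, 102L)
  expect_equal(ht$k, 20L)
  expect_equal(unname(ht$parameter), 101)
  # proportion exactly at the null value: centered
  ht0 <- uscore_proportion_test(c(rep(0.01, 5), seq(0.2, 0.9, length.out = 95)),
                                0.05)
  expect_equal(unname(ht0$statistic), 0)
  expect_equal(ht0$p.value, 0.5)
  # degenerate indicator vectors are refused
  expect_error(uscore_proportion_test(rep(0.9, 10), 0.05), "zero variance")
  expect_error(uscore_proportion_test(0.3, 0.5), "at least 2")
})

test_that("growing the universe by a non-member makes overlap more surprising", {
  # with candidates, set and overlap fixed, enlarging L can only shrink the
  # chance of drawing K set genes, so the tail probability is non-increasing
  set.seed(13)
  for (i in 1:20) {
    L <- sample(20:60, 1); S <- sample(3:10, 1); l <- sample(5:15, 1)
    K <- sample(0:min(l, S), 1)
    expect_lte(hypergeom_upper_p(L + 1, l, S, K),
               hypergeom_upper_p(L, l, S, K) + 1e-12)
  }
})
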