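test_that("estimate_scores: additivity, purity transform and identical sets", {
  m <- rand_expr(100, 8, seed = 41)
  stromal <- rownames(m)[1:10]
  immune <- rownames(m)[11:20]
  est <- estimate_scores(m, stromal, immune)
  expect_equal(est$estimate_score, est$stromal_score + est$immune_score,
               tolerance = 1e-12)
  expect_equal(est$purity_raw,
               cos(0.6049872018 + 0.0001467884 * est$estimate_score))
  expect_true(all(est$tumor_purity >= 0 & est$tumor_purity <= 1))

  same <- estimate_scores(m, stromal, stromal)
  expect_equal(same$stromal_score, same$immune_score)

  expect_error(estimate_scores(m, character(0), immune), "empty stromal")
})

test_that("purity at estimate_score 0 is cos(0.6049872018) and the transform
           is monotone decreasing on the principal branch", {
  expect_equal(cos(0.6049872018), 0.822, tolerance = 1e-3)
  es <- seq(0, (pi - 0.6049872018) / 0.0001467884, length.out = 50)
  pur <- cos(0.6049872018 + 0.0001467884 * es)
  expect_true(all(diff(pur) < 0))
})

test_that("moderated_t_deg recovers planted genes and applies the printed
           significance rule", {
  set.seed(42)
  n <- 50
  m <- matrix(rnorm(500 * 2 * n, 6, 0.5), nrow = 500)
  groups <- rep(c("low", "high"), each = n)
  m[1:50, groups == "high"] <- m[1:50, groups == "high"] + 1  # planted logFC 1
  dimnames(m) <- list(sprintf("g%03d", 1:500), sprintf("s%03d", 1:(2 * n)))
  deg <- moderated_t_deg(m, groups)
  expect_equal(deg$gene, rownames(m))
  expect_equal(mean(deg$logFC[1:50]), 1, tolerance = 0.1)
  expect_gte(mean(deg$significant[1:50]), 0.95)   # recall on planted genes
  # significance is exactly the printed conjunction, BH never filters
  expect_equal(deg$significant,
               abs(deg$logFC) > 0.5 & deg$p_value < 0.05)
  expect_true(all(deg$bh_adjusted_p >= deg$p_value - 1e-12))
})

test_that("zero-variance genes are excluded with a warning", {
  m <- rand_expr(20, 10, seed = 43)
  m[3, ] <- 7
  groups <- rep(c("low", "high"), each = 5)
  expect_warning(deg <- moderated_t_deg(m, groups), "zero variance")
  expect_equal(nrow(deg), 19)
  expect_false("g003" %in% deg$gene)
  expect_error(moderated_t_deg(m[, 1:6], rep(c("low", "high"), c(5, 1))),
               "2 samples per group")
})

test_that("moderated t converges to the pooled two-sample t at large n", {
  # heterogeneous gene variances (the shrinkage model's own prior): with a
  # finite prior df, the squeeze weight vanishes as the per-gene df grows
  set.seed(44)
  n <- 200
  sd_g <- sqrt(4 / rchisq(300, df = 4))
  m <- 6 + matrix(rnorm(300 * 2 * n, 0, rep(sd_g, 2 * n)), nrow = 300,
                  dimnames = list(sprintf("g%03d", 1:300), NULL))
  colnames(m) <- sprintf("s%03d", 1:(2 * n))
  groups <- rep(c("low", "high"), each = n)
  deg <- moderated_t_deg(m, groups)
  plain_t <- apply(m, 1, function(x)
    t.test(x[groups == "high"], x[groups == "low"], var.equal = TRUE)$statistic)
  expect_lt(max(abs(deg$t - plain_t)), 0.05)
})

test_that("ranked_enrichment flags an extreme set and is deterministic", {
  set.seed(45)
  stat <- setNames(rnorm(1000), sprintf("g%04d", 1:1000))
  top <- names(sort(stat, decreasing = TRUE))[1:10]
  sets <- gene_set_collection(list(top = top,
                                   rand = sample(names(stat), 30)))
  r1 <- ranked_enrichment(stat, sets, n_perm = 1000, seed = 9)
  expect_gt(r1$ES[r1$set == "top"], 0)
  expect_equal(r1$p_value[r1$set == "top"], 1 / 1001, tolerance = 1e-12)
  expect_gt(r1$p_value[r1$set == "rand"], 0.01)

  r2 <- ranked_enrichment(stat, sets, n_perm = 1000, seed = 9)
  expect_identical(r1, r2)

  all_genes <- gene_set_collection(list(all = names(stat)))
  expect_error(ranked_enrichment(stat, all_genes, n_perm = 100),
               "covers all ranked genes")
  expect_error(ranked_enrichment(stat, sets, n_perm = 10), ">= 100")
})

test_that("ranked_enrichment null p-values are near-uniform", {
  set.seed(46)
  stat <- setNames(rnorm(400), sprintf("g%04d", 1:400))
  ps <- vapply(1:60, function(i) {
    sets <- gene_set_collection(list(s = sample(names(stat), 15)))
    ranked_enrichment(stat, sets, n_perm = 200, seed = i)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the ES depends on the weight profile, not only the ranking", {
  # a strictly monotone transform of the statistic changes |stat| weights
  # and hence the ES: document that the score is weight-dependent
  set.seed(47)
  stat <- setNames(abs(rnorm(200)) + 0.1, sprintf("g%03d", 1:200))
  sets <- gene_set_collection(list(s = sample(names(stat), 12)))
  e1 <- ranked_enrichment(stat, sets, n_perm = 100, seed = 1)$ES
  e2 <- ranked_enrichment(stat^3, sets, n_perm = 100, seed = 1)$ES
  expect_false(isTRUE(all.equal(e1, e2)))
})

test_that("ranked_enrichment agrees with fgsea on direction and significance", {
  skip_if_not_installed("fgsea")
  set.seed(48)
  stat <- setNames(rnorm(500), sprintf("g%04d", 1:500))
  top <- names(sort(stat, decreasing = TRUE))[1:15]
  bottom <- names(sort(stat))[1:15]
  sets <- gene_set_collection(list(up = top, down = bottom))
  mine <- ranked_enrichment(stat, sets, n_perm = 500, seed = 2)
  ref <- suppressWarnings(fgsea::fgseaSimple(
    pathways = sets$genes, stats = stat, nperm = 500, gseaParam = 1))
  expect_equal(sign(mine$ES), sign(ref$ES[match(mine$set, ref$pathway)]))
  expect_lt(mine$p_value[mine$set == "up"], 0.01)
  expect_lt(mine$p_value[mine$set == "down"], 0.01)
})

test_that("group_compare: exact enumeration and error contracts", {
  r <- group_compare(c(1, 2, 3, 4, 5, 6),
                     rep(c("high", "low"), each = 3))
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)   # 2/20 orderings as extreme
  expect_error(group_compare(1:3, c("a", "a", "b")), "at least 4")
  expect_error(group_compare(1:4, rep("a", 4)), "two groups")
})

test_that("group_compare holds its size under the null", {
  set.seed(49)
  rej <- mean(replicate(1000, {
    group_compare(rnorm(60), rep(c("a", "b"), 30))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.015)
})
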