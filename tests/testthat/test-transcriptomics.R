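test_that("75th-percentile normalization equalizes samples and is idempotent", {
  set.seed(3)
  m <- matrix(rlnorm(5000, 6, 1), nrow = 500)
  norm <- normalize_75th(m)
  q <- apply(norm, 2, quantile, probs = 0.75)
  expect_lt(diff(range(q)), 1e-9)
  expect_equal(normalize_75th(norm), norm, tolerance = 1e-12)  # fixed point
  # per-sample scale invariance: rescaling one of the 10 samples is undone
  # up to the global factor it contributes to the geometric-mean target
  m2 <- m
  m2[, 3] <- 10 * m2[, 3]
  expect_equal(normalize_75th(m2) / 10^(1 / 10), norm, tolerance = 1e-12)
  expect_error(normalize_75th(matrix(c(-1, 2, 3, 4), 2)), "positive")
})

test_that("Welch statistics match stats::t.test per probe to 1e-10", {
  g <- gen_expression(n_probes = 200, n_per_group = 5, n_de = 20, lfc = 1,
                      seed = 2)
  de <- welch_de(g$matrix, g$groups)
  lx <- log2(g$matrix)
  for (i in sample.int(200, 25)) {
    ref <- t.test(lx[i, g$groups == "treated"], lx[i, g$groups == "vehicle"],
                  var.equal = FALSE)
    expect_lt(abs(de$p[i] - ref$p.value), 1e-10)
    expect_lt(abs(de$t[i] - unname(ref$statistic)), 1e-10)
    expect_lt(abs(de$df[i] - unname(ref$parameter)), 1e-8)
  }
  # fold change is the ratio of linear-scale geometric means
  i <- 1
  gm <- function(x) exp(mean(log(x)))
  expect_equal(de$fold_change[i],
               gm(g$matrix[i, g$groups == "treated"]) /
                 gm(g$matrix[i, g$groups == "vehicle"]),
               tolerance = 1e-12)
  # BH q-values: valid and monotone in p-rank order, q >= p
  expect_true(all(de$q >= de$p - 1e-15))
  ord <- order(de$p)
  expect_true(all(diff(de$q[ord]) >= -1e-15))
})

test_that("welch_de rejects degenerate group layouts and handles flat probes", {
  g <- gen_expression(n_probes = 10, n_per_group = 3, seed = 1)
  expect_error(welch_de(g$matrix, rep("treated", 6)), "two labels")
  expect_error(welch_de(g$matrix[, 1:4], c("vehicle", "treated", "treated",
                                           "treated")), "at least 2")
  flat <- matrix(4, nrow = 2, ncol = 6)
  de <- welch_de(flat, rep(c("vehicle", "treated"), each = 3))
  expect_equal(de$p, c(1, 1))
  expect_equal(de$fold_change, c(1, 1))
})

test_that("classification uses strict fold-change and p cutoffs", {
  de <- data.frame(probe = c("a", "b", "c", "d"),
                   fold_change = c(2.0, 2.01, 0.49, 1.0),
                   p = c(0.001, 0.001, 0.02, 0.5))
  cl <- classify_de(de)
  expect_equal(cl$up, "b")          # fc exactly 2 excluded
  expect_equal(cl$down, character(0))  # p 0.02 fails p < 0.01
  # planted probes are recovered at large effect
  g <- gen_expression(n_probes = 1000, n_per_group = 8, n_de = 40, lfc = 2,
                      sd_log2 = 0.5, seed = 6)
  cl2 <- classify_de(welch_de(g$matrix, g$groups))
  found <- c(cl2$up, cl2$down)
  expect_setequal(found, rownames(g$matrix)[g$truth])
})

test_that("ddct reproduces the 2^-ddCt identities", {
  rec <- data.frame(sample = 1:6,
                    group = rep(c("ctrl", "trt"), each = 3),
                    ct_target = c(25, 25, 25, 26, 26, 26),
                    ct_reference = 20)
  out <- ddct(rec, "ctrl")
  expect_equal(out$fold[out$group == "ctrl"], 1)
  expect_equal(out$fold[out$group == "trt"], 0.5)  # one cycle later = half
  rec2 <- rec
  rec2$ct_target[4:6] <- 23                        # ddCt = -2
  expect_equal(ddct(rec2, "ctrl")$fold[2], 4)
  # multiplicativity: fold(a+b) = fold(a) * fold(b)
  f <- function(shift) {
    r <- rec; r$ct_target[4:6] <- 25 + shift; ddct(r, "ctrl")$fold[2]
  }
  expect_equal(f(1.3 + 0.9), f(1.3) * f(0.9), tolerance = 1e-12)
  expect_error(ddct(rec, "nope"), "control group")
  rec$ct_reference[1] <- NA
  expect_error(ddct(rec, "ctrl"), "reference")
})

test_that("enrichment score equals the brute-force running-sum oracle", {
  set.seed(8)
  for (i in 1:10) {
    n <- 1000
    metric <- setNames(rnorm(n), sprintf("g%04d", 1:n))
    set <- sample(names(metric), 50)
    es <- enrichment_score(metric, set)
    expect_equal(es$es, oracle_es(metric, set), tolerance = 1e-12)
    expect_lte(abs(es$es), 1)
    # the fast positional form used by the permutation engine agrees too
    ranked <- sort(metric, decreasing = TRUE)
    idx <- which(names(ranked) %in% set)
    expect_equal(phosreg:::.es_from_positions(idx, abs(ranked), n),
                 es$es, tolerance = 1e-12)
  }
})

test_that("enrichment score boundary and error behaviour", {
  n <- 600
  metric <- setNames(sort(rnorm(n), decreasing = TRUE), sprintf("g%03d", 1:n))
  top <- names(metric)[1:50]
  es <- enrichment_score(metric, top, p = 0)
  expect_gt(es$es, 0.9)   # members fill the top ranks
  expect_error(enrichment_score(metric, names(metric)), "complement")
  expect_error(enrichment_score(metric, c("zz1", "zz2")), "no member")
})

test_that("enrichment score agrees with fgsea's statistic", {
  skip_if_not_installed("fgsea")
  set.seed(11)
  metric <- setNames(rnorm(800), sprintf("g%04d", 1:800))
  set <- sample(names(metric), 40)
  es <- enrichment_score(metric, set, p = 1)
  ranked <- sort(metric, decreasing = TRUE)
  ref <- fgsea::calcGseaStat(ranked,
                             selectedStats = which(names(ranked) %in% set),
                             gseaParam = 1, scoreType = "std")
  expect_equal(es$es, ref, tolerance = 1e-8)
})

test_that("gene-wise permutation GSEA is seeded and calibrated", {
  g <- gen_expression(n_probes = 1500, n_per_group = 6, n_de = 60, lfc = 2,
                      seed = 4)
  sets <- gen_gene_sets(rownames(g$matrix), n_sets = 5, set_size = 40,
                        seed = 2)
  # a set made of the most up-shifted planted probes is maximally significant
  up_probes <- rownames(g$matrix)[g$true_lfc > 0]
  sets$PLANTED_UP <- up_probes
  r1 <- gsea_genewise(g$matrix, g$groups, sets, n_perm = 500, seed = 9)
  r2 <- gsea_genewise(g$matrix, g$groups, sets, n_perm = 500, seed = 9)
  expect_identical(r1, r2)                              # seeded determinism
  planted <- r1[r1$set == "PLANTED_UP", ]
  expect_gt(planted$es, 0)
  expect_lte(planted$p_perm, 1 / 250)
  expect_lte(planted$fdr_q, 0.05)
  expect_error(gsea_genewise(g$matrix, g$groups, sets, n_perm = 0), "n_perm")
})

test_that("GSEA permutation p-values are uniform on null data", {
  g0 <- gen_expression(n_probes = 1200, n_per_group = 6, n_de = 0, seed = 14)
  sets <- gen_gene_sets(rownames(g0$matrix), n_sets = 100, set_size = 30,
                        seed = 3)
  res <- gsea_genewise(g0$matrix, g0$groups, sets, n_perm = 200, seed = 5)
  frac <- mean(res$p_perm < 0.05)
  # binomial 99% envelope around 0.05 for 100 sets
  expect_lte(frac, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 100))
})
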