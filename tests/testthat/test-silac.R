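test_that("class-I filter keeps STY sites at or above the probability cutoff", {
  rec <- data.frame(
    residue = c("Y", "S", "H", "T", "S"),
    localization_prob = c(0.75, 0.74, 0.99, 1.0, NA),
    stringsAsFactors = FALSE
  )
  out <- filter_class1(rec)
  expect_equal(out$residue, c("Y", "T"))          # boundary 0.75 inclusive
  expect_equal(nrow(filter_class1(rec, min_prob = 0.5)), 3)
  expect_equal(nrow(filter_class1(rec[0, ])), 0)  # empty output allowed
})

test_that("label-swap harmonization inverts once and only once", {
  rec <- data.frame(ratio_rep1 = c(1, 1, 1), ratio_rep2 = c(2.0, 1.0, 0.679))
  attr(rec, "rep2_swapped") <- TRUE
  h1 <- harmonize_label_swap(rec)
  expect_equal(h1$ratio_rep2, c(0.5, 1.0, 1 / 0.679))
  h2 <- harmonize_label_swap(h1)                   # idempotent via state flag
  expect_identical(h1, h2)

  plain <- data.frame(ratio_rep1 = 1, ratio_rep2 = 0.679)
  expect_equal(harmonize_label_swap(plain)$ratio_rep2, 0.679)  # pass-through

  bad <- data.frame(ratio_rep1 = 1, ratio_rep2 = -1)
  attr(bad, "rep2_swapped") <- TRUE
  expect_error(harmonize_label_swap(bad), "positive")
})

test_that("Gaussian histogram regression recovers the generator sigma", {
  d <- gen_silac_dataset(silac_sim_config(n_sites = 20000, frac_regulated = 0,
                                          null_sigma_log2 = 0.223, seed = 7))
  rec <- harmonize_label_swap(d$records)
  null <- fit_gaussian_null(rec, mode = "pooled_single_ratios")
  expect_lt(abs(null$sigma_log2 - 0.223), 0.01)
  expect_lt(abs(null$mu_log2), 0.01)

  # fitting is deterministic
  null2 <- fit_gaussian_null(rec, mode = "pooled_single_ratios")
  expect_identical(c(null$mu_log2, null$sigma_log2),
                   c(null2$mu_log2, null2$sigma_log2))

  # ratio-of-ratios sd is sqrt(2) x the replicate-noise component
  rr <- fit_gaussian_null(rec, mode = "ratio_of_ratios")
  expect_lt(abs(rr$sigma_log2 - sqrt(2) * 0.10), 0.01)
})

test_that("degenerate or undersized samples are rejected by the null fit", {
  flat <- data.frame(ratio_rep1 = rep(1, 200), ratio_rep2 = rep(1, 200))
  attr(flat, "harmonized") <- TRUE
  expect_error(fit_gaussian_null(flat), "degenerate")
  small <- data.frame(ratio_rep1 = runif(50, 0.5, 2),
                      ratio_rep2 = runif(50, 0.5, 2))
  attr(small, "harmonized") <- TRUE
  expect_error(fit_gaussian_null(small), "100 sites")
})

test_that("threshold derivation matches the closed form", {
  thr <- derive_thresholds(list(mu_log2 = 0, sigma_log2 = 0.2233), k = 2.5)
  expect_equal(round(thr$up_thr, 3), 1.472)
  expect_equal(round(thr$down_thr, 3), 0.679)
  expect_equal(thr$up_thr * thr$down_thr, 1)       # mu = 0 symmetry, exact

  thr2 <- derive_thresholds(list(mu_log2 = 0.1, sigma_log2 = 0.2), k = 2.5)
  expect_equal(thr2$up_thr * thr2$down_thr, 2^0.2) # product identity
  expect_error(derive_thresholds(list(mu_log2 = 0, sigma_log2 = 0.2), k = 0),
               "positive")
})

test_that("published ratio pairs classify as printed under the printed thresholds", {
  rec <- data.frame(
    gene = c("MAPK1", "RPS6KA1", "X"),
    position = c(187L, 741L, 1L),
    residue = c("Y", "S", "S"),
    ratio_rep1 = c(0.34, 1.16, 0.5),
    ratio_rep2 = c(0.47, 0.87, 1.6),
    stringsAsFactors = FALSE
  )
  attr(rec, "harmonized") <- TRUE
  calls_t <- call_regulation(rec[1, ], thr_tmd8)
  expect_equal(as.character(calls_t$direction), "down")
  calls_u <- call_regulation(rec[2, ], thr_u2932)
  expect_equal(as.character(calls_u$direction), "unchanged")
  # discordant directions are never regulated, whatever the thresholds
  expect_equal(as.character(call_regulation(rec[3, ], thr_tmd8)$direction),
               "unchanged")
})

test_that("regulation calls agree with the per-site brute-force oracle", {
  for (seed in c(1, 2, 3)) {
    d <- gen_silac_dataset(silac_sim_config(n_sites = 3000,
                                            frac_regulated = 0.05,
                                            seed = seed))
    rec <- harmonize_label_swap(d$records)
    # inject missing values to exercise the missing-replicate rule
    set.seed(seed)
    rec$ratio_rep2[sample.int(nrow(rec), 50)] <- NA
    thr <- derive_thresholds(fit_gaussian_null(rec))
    calls <- call_regulation(rec, thr)
    expect_identical(as.character(calls$direction),
                     oracle_direction(rec$ratio_rep1, rec$ratio_rep2, thr))
  }
})

test_that("raising k never increases the number of regulated sites", {
  d <- gen_silac_dataset(silac_sim_config(n_sites = 5000,
                                          frac_regulated = 0.05, seed = 13))
  rec <- harmonize_label_swap(d$records)
  null <- fit_gaussian_null(rec)
  n_reg <- vapply(c(1, 1.5, 2, 2.5, 3, 4), function(k) {
    sum(call_regulation(rec, derive_thresholds(null, k))$direction != "unchanged")
  }, numeric(1))
  expect_true(all(diff(n_reg) <= 0))
})

test_that("pure-null data yields well under 1% regulated calls", {
  d <- gen_silac_dataset(silac_sim_config(n_sites = 20000, frac_regulated = 0,
                                          seed = 17))
  rec <- harmonize_label_swap(d$records)
  calls <- call_regulation(rec, derive_thresholds(fit_gaussian_null(rec)))
  expect_lt(mean(calls$direction != "unchanged"), 0.01)
})

test_that("regulation summary counts sites, proteins and percentages", {
  pub <- published_calls()
  shared_only <- pub$u2932[1:5, ]                  # the five shared-down rows
  s <- summarize_regulation(shared_only, n_quantified = 5)
  expect_equal(s$n_down_sites, 5)
  expect_equal(s$n_down_proteins, 5)
  expect_equal(s$pct_down, 100)

  empty <- call_regulation({
    r <- data.frame(gene = character(), position = integer(),
                    residue = character(), ratio_rep1 = numeric(),
                    ratio_rep2 = numeric())
    attr(r, "harmonized") <- TRUE
    r
  }, thr_tmd8)
  s0 <- summarize_regulation(empty, n_quantified = 100)
  expect_equal(c(s0$n_down_sites, s0$n_up_sites, s0$pct_down), c(0, 0, 0))
  expect_error(summarize_regulation(empty, n_quantified = 0), "positive")

  # distinct-protein counting: two sites on one gene collapse to one protein
  two <- data.frame(gene = c("A", "A", "B"), position = c(1L, 2L, 3L),
                    residue = "S", ratio_rep1 = 0.3, ratio_rep2 = 0.3)
  attr(two, "harmonized") <- TRUE
  s2 <- summarize_regulation(call_regulation(two, thr_tmd8))
  expect_equal(s2$n_down_sites, 3)
  expect_equal(s2$n_down_proteins, 2)
})

test_that("residue composition reports one-decimal percentages", {
  rec <- data.frame(residue = c(rep("S", 846), rep("T", 144), rep("Y", 10)))
  expect_equal(residue_composition(rec), c(S = 84.6, T = 14.4, Y = 1.0))
  expect_equal(residue_composition(data.frame(residue = rep("S", 7))),
               c(S = 100, T = 0, Y = 0))
  expect_error(residue_composition(data.frame(residue = character())), "empty")
})

test_that("overlap of published call sets recovers exactly the five shared sites", {
  pub <- published_calls()
  ov <- overlap_regulated(pub$tmd8, pub$u2932, "down")
  expect_equal(nrow(ov), 5)
  expect_setequal(paste(ov$gene, ov$position, ov$residue),
                  c("ITPKB 43 S", "BET1 50 S", "VAPB 158 S",
                    "MAPK1 187 Y", "ADRBK1 685 S"))

  # identical sets return everything; disjoint sets return nothing
  all_down <- overlap_regulated(pub$tmd8, pub$tmd8, "down")
  expect_equal(nrow(all_down), sum(pub$tmd8$direction == "down"))
  expect_equal(nrow(overlap_regulated(pub$tmd8[0, ], pub$u2932, "down")), 0)
})
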