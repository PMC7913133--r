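null_config <- function(seed, n_bio = 3L, noise = 0.2) {
  sim_ct_config(genes = c(PSY4 = 1), seed = seed, n_bio = n_bio,
                noise_sd = noise)
}

test_that("technical replicates collapse by arithmetic mean", {
  tab <- data.frame(gene = "g", group = "a", bio_rep = c(1, 1, 2),
                    tech_rep = c(1, 2, 1), ct = c(20.0, 20.4, 25))
  col <- collapse_technical(tab)
  expect_equal(col$ct, c(20.2, 25))
  # recount oracle on random tables
  set.seed(91)
  for (rep in 1:10) {
    g <- gen_ct_table(sim_ct_config(genes = c(A = 2, B = 0.5), seed = rep,
                                    n_bio = 4, n_tech = 3))
    col <- collapse_technical(g$table)
    for (r in seq_len(nrow(col))) {
      sel <- g$table[g$table$gene == col$gene[r] &
                     g$table$group == col$group[r] &
                     g$table$bio_rep == col$bio_rep[r], ]
      expect_equal(col$ct[r], mean(sel$ct))
    }
  }
})

test_that("delta-delta-Ct closed forms: null and one-cycle shift", {
  base <- expand.grid(gene = c("PSY4", "actin-2"),
                      group = c("control", "treated"),
                      bio_rep = 1:3, tech_rep = 1:2,
                      stringsAsFactors = FALSE)
  base$ct <- 24
  r0 <- ddct_ratio(ct_table(base), "PSY4", "treated", "control")
  expect_equal(r0$ddct, 0)
  expect_equal(r0$ratio, 1)

  shifted <- base
  shifted$ct[shifted$gene == "PSY4" & shifted$group == "treated"] <- 23
  r1 <- ddct_ratio(ct_table(shifted), "PSY4", "treated", "control")
  expect_equal(r1$ddct, -1)
  expect_equal(r1$ratio, 2)
  # efficiency hook: ratio = efficiency^(-ddct)
  r15 <- ddct_ratio(ct_table(shifted), "PSY4", "treated", "control",
                    efficiency = 1.5)
  expect_equal(r15$ratio, 1.5)

  noref <- base[base$gene != "actin-2" | base$group != "treated", ]
  expect_error(ct_table(noref), "actin-2")
})

test_that("noise-free generator obeys the Ct closed form", {
  g <- gen_ct_table(sim_ct_config(genes = c(PSY4 = 2), seed = 1,
                                  noise_sd = 0, ct_base = 24))
  tab <- g$table
  tc <- tab$ct[tab$gene == "PSY4" & tab$group == "control"]
  tt <- tab$ct[tab$gene == "PSY4" & tab$group == "treated"]
  expect_true(all(tc == 24))
  expect_true(all(tt == 23))
  est <- ddct_ratio(tab, "PSY4", "treated", "control")
  expect_equal(est$ratio, 2)
})

test_that("a true fold change of 4 is recovered within 5% on average", {
  ratios <- vapply(1:200, function(s) {
    g <- gen_ct_table(sim_ct_config(genes = c(PSY4 = 4), seed = 1000 + s,
                                    noise_sd = 0.2))
    ddct_ratio(g$table, "PSY4", "treated", "control")$ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 4) / 4, 0.05)
})

test_that("randomization p-values are reproducible, bounded and exact on ties", {
  g <- gen_ct_table(sim_ct_config(genes = c(PSY4 = 4), seed = 9))
  p1 <- randomization_test(g$table, "PSY4", "treated", "control",
                           n_permutations = 499, seed = 5)
  p2 <- randomization_test(g$table, "PSY4", "treated", "control",
                           n_permutations = 499, seed = 5)
  expect_identical(p1$p_value, p2$p_value)
  expect_gte(p1$p_value, 1 / 500)

  flat <- expand.grid(gene = c("PSY4", "actin-2"),
                      group = c("control", "treated"),
                      bio_rep = 1:3, tech_rep = 1:2,
                      stringsAsFactors = FALSE)
  flat$ct <- 30
  pflat <- randomization_test(ct_table(flat), "PSY4", "treated", "control",
                              n_permutations = 200, seed = 1)
  expect_identical(pflat$p_value, 1)

  one_rep <- flat[flat$bio_rep == 1, ]
  expect_error(randomization_test(ct_table(one_rep), "PSY4", "treated",
                                  "control"),
               ">= 2 biological replicates")
})

test_that("randomization test holds its size under the null", {
  # 6 biological replicates per group give the permutation distribution
  # enough resolution to reject at the 5% level at all
  rejections <- vapply(1:500, function(s) {
    g <- gen_ct_table(null_config(2000 + s, n_bio = 6L))
    randomization_test(g$table, "PSY4", "treated", "control",
                       n_permutations = 199, seed = s)$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("bootstrap interval is ordered and covers a true ratio near nominal", {
  g <- gen_ct_table(sim_ct_config(genes = c(PSY4 = 4), seed = 13))
  ci <- ddct_bootstrap_ci(g$table, "PSY4", "treated", "control",
                          n_boot = 500, seed = 3)
  expect_lte(ci$ci_low, ci$ci_high)

  cover <- vapply(1:400, function(s) {
    g <- gen_ct_table(sim_ct_config(genes = c(PSY4 = 4), seed = 5000 + s,
                                    n_bio = 10L, noise_sd = 0.2))
    ci <- ddct_bootstrap_ci(g$table, "PSY4", "treated", "control",
                            n_boot = 300, level = 0.9, seed = s)
    ci$ci_low <= 4 && 4 <= ci$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.85)
  expect_lte(mean(cover), 0.95)
})

test_that("the one-call analysis wrapper assembles all components", {
  g <- gen_ct_table(sim_ct_config(genes = c(PSY4 = 4), seed = 17))
  res <- ddct_analysis(g$table, "PSY4", "treated", "control",
                       n_permutations = 499, n_boot = 400, seed = 2)
  expect_identical(nrow(res), 1L)
  expect_equal(res$ratio, 2^(-res$ddct))
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_lte(res$ci_low, res$ci_high)
})
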