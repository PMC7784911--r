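test_that("QC exclusions reproduce the analysable cohort bookkeeping", {
  m <- recruitment_manifest()
  expect_equal(nrow(m), 102)
  expect_equal(as.integer(table(m$group)[c("PD", "CP", "CN")]), c(51L, 17L, 34L))
  res <- apply_exclusions(m)
  expect_equal(res$report$n_analysable, 95)
  expect_equal(res$report$n_excluded, 7)
  expect_equal(as.integer(res$report$analysable_by_group[c("PD", "CN", "CP")]),
               c(49L, 31L, 15L))
  per_reason <- tapply(res$report$per_reason_group$n,
                       res$report$per_reason_group$reason, sum)
  expect_equal(as.integer(per_reason[c("incomplete_scan", "injection_failure",
                                      "nonphysiological_vp")]), c(2L, 3L, 2L))
})

test_that("exclusions are identity with no flags and total with all flags", {
  m <- recruitment_manifest()
  clean <- m
  clean$incomplete_scan <- clean$injection_failure <- clean$nonphysiological_vp <- FALSE
  expect_equal(nrow(apply_exclusions(clean)$manifest), nrow(m))
  all_bad <- m; all_bad$incomplete_scan <- TRUE
  res <- apply_exclusions(all_bad)
  expect_equal(nrow(res$manifest), 0)
  expect_equal(res$report$n_recruited, nrow(m))
  dup <- m; dup$subject[2] <- dup$subject[1]
  expect_error(apply_exclusions(dup), "duplicate")
})

test_that("identical groups give t = 0, p = 1 in demographic comparisons", {
  subs <- tibble::tibble(subject = sprintf("S%02d", 1:20),
                         group = rep(c("A", "B"), each = 10),
                         age = rep(c(60, 62, 64, 66, 68), 4),
                         gender = rep(c("F", "M"), 10))
  out <- demographic_tests(subs, continuous = "age", categorical = "gender")
  age_row <- out[out$variable == "age", ]
  expect_equal(age_row$statistic, 0)
  expect_equal(age_row$p, 1)
  expect_equal(out$p[out$variable == "gender"], 1)
})

test_that("Fisher exact p matches full hypergeometric enumeration", {
  # independent oracle: sum the point probabilities of all tables with the
  # same margins whose probability does not exceed the observed one
  fisher_enum <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    pr <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
    p_obs <- pr[support == tab[1, 1]]
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  }
  tab <- matrix(c(1, 9, 9, 1), 2, byrow = TRUE)
  expect_equal(fisher_enum(tab), 202 / 184756, tolerance = 1e-12)
  expect_equal(fisher.test(tab)$p.value, 202 / 184756, tolerance = 1e-9)
  # oracle sweep over random tables with N <= 40
  set.seed(9)
  for (i in 1:25) {
    t2 <- matrix(rpois(4, 5), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    expect_equal(fisher.test(t2)$p.value, fisher_enum(t2), tolerance = 1e-9)
    expect_equal(fisher.test(t2[2:1, ])$p.value, fisher.test(t2)$p.value,
                 tolerance = 1e-12)
  }
  # demographic_tests wires the same test: check against the oracle
  subs <- tibble::tibble(subject = sprintf("S%02d", 1:20),
                         group = rep(c("A", "B"), each = 10),
                         gender = c(rep("F", 1), rep("M", 9),
                                    rep("F", 9), rep("M", 1)))
  out <- demographic_tests(subs, continuous = character(0),
                           categorical = "gender")
  expect_equal(out$p, 202 / 184756, tolerance = 1e-9)
})

test_that("mixed-model group F matches the split-plot sums-of-squares oracle", {
  # balanced complete design, no covariates: the group F of the mixed model
  # equals MS_group / MS_subject-within-group from the textbook decomposition
  d <- cohort_design(group_sizes = c(CN = 10, CP = 10, PD = 10),
                     mean_ktrans = null_means_ktrans(1),
                     mean_vp = null_means_vp(), seed = 21)
  co <- generate_cohort(d)
  a <- rm_anova(co, "ktrans")
  dd <- co[co$metric == "ktrans", ]
  n_r <- length(unique(dd$region))
  subj_means <- aggregate(value ~ subject + group, dd, mean)
  grand <- mean(dd$value)
  n_per_g <- table(subj_means$group)
  g_means <- tapply(subj_means$value, subj_means$group, mean)
  ss_group <- n_r * sum(n_per_g * (g_means - grand)^2)
  ss_subj <- n_r * sum((subj_means$value - g_means[subj_means$group])^2)
  df_g <- 3 - 1
  df_s <- sum(n_per_g) - 3
  f_oracle <- (ss_group / df_g) / (ss_subj / df_s)
  grp <- a$table[a$table$term == "group", ]
  expect_equal(grp$F, f_oracle, tolerance = 1e-6)
  expect_equal(grp$df_num, df_g)
  expect_equal(grp$df_den, df_s, tolerance = 1e-3)
})

test_that("a singular mixed fit falls back to fixed effects with a warning", {
  d <- cohort_design(group_sizes = c(CN = 4, CP = 4, PD = 4),
                     between_subject_sd = c(ktrans = 0, vp = 0),
                     within_subject_sd = c(ktrans = 1e-4, vp = 1e-4), seed = 5)
  co <- generate_cohort(d)
  expect_warning(a <- rm_anova(co, "ktrans"), "singular|fixed-effects")
  expect_true(all(c("group", "region") %in% a$table$term))
})

test_that("Bonferroni correction multiplies by the number of pairs and caps at 1", {
  d <- cohort_design(group_sizes = c(CN = 8, CP = 8, PD = 8),
                     mean_ktrans = null_means_ktrans(0),
                     mean_vp = null_means_vp(), seed = 11)
  co <- generate_cohort(d)
  ph <- posthoc_pairwise(co, "ktrans")
  expect_equal(nrow(ph$overall), 3)
  expect_equal(ph$overall$p_bonferroni,
               pmin(1, 3 * ph$overall$p_raw), tolerance = 1e-12)
  expect_true(all(ph$overall$p_bonferroni >= ph$overall$p_raw))
  expect_equal(nrow(ph$by_region), 8 * 3)
})

test_that("a strong medication effect on vp is detected by the clinical model", {
  d <- cohort_design(seed = 31)
  co <- generate_cohort(d)
  # inject vp increasing with LEDD, slope far above noise
  subs <- cohort_subjects(co)
  led <- subs$ledd[match(co$subject, subs$subject)]
  sel <- co$group == "PD" & co$metric == "vp"
  co$value[sel] <- co$value[sel] + 3e-5 * led[sel]
  res <- clinical_lmm(co, "vp")
  expect_lt(res$table$p[res$table$term == "ledd"], 0.01)
  expect_true(all(c("region", "moca", "ledd", "updrs",
                    "region:moca", "region:ledd", "region:updrs")
                  %in% res$table$term))
})

test_that("clinical model type-I error for the medication term is nominal", {
  # null: no LEDD effect; moderate replicate count keeps runtime low and the
  # binomial check loose accordingly
  set.seed(17)
  hits <- 0; nrep <- 60
  for (i in seq_len(nrep)) {
    co <- generate_cohort(cohort_design(group_sizes = c(CN = 2, CP = 2, PD = 20),
                                        seed = 1000 + i))
    res <- clinical_lmm(co, "vp")
    hits <- hits + (res$table$p[res$table$term == "ledd"] < 0.05)
  }
  expect_lt(hits / nrep, 0.15)
})

test_that("zero-variance responses and constant predictors are handled", {
  co <- generate_cohort(cohort_design(seed = 41))
  co0 <- co
  co0$value[co0$metric == "vp"] <- 1
  expect_error(clinical_lmm(co0, "vp"), "zero variance")
  co2 <- co
  co2$ledd[co2$group == "PD"] <- 500
  expect_warning(res <- clinical_lmm(co2, "vp"), "constant predictor")
  expect_false("ledd" %in% res$table$term)
})
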