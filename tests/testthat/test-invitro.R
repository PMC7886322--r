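# In vitro analysis: specimen metrics, summary table, nonparametric tests.

test_that("specimen_metrics recovers closed-form values on a linear curve", {
  cv <- linear_failure_curve(slope = 150, csa = 30, gauge = 60, fail_force = 1500)
  m <- specimen_metrics(cv)
  expect_equal(m$stiffness_n_mm, 150, tolerance = 1e-6)
  expect_equal(m$modulus_mpa, 150 * 60 / 30, tolerance = 1e-6)
  expect_equal(m$failure_force_n, 1500, tolerance = 1e-6)
  expect_equal(m$ultimate_stress_mpa, 50, tolerance = 1e-6)
  expect_equal(m$ultimate_strain_pct, 1500 / 150 / 60 * 100, tolerance = 1e-6)
})

test_that("ultimate stress reproduces a printed specimen cell within rounding", {
  # specimen 85-F lateral gastrocnemius: CSA 10.4 mm^2, failure 787.5 N
  cv <- linear_failure_curve(slope = 151.7, csa = 10.4, fail_force = 787.5)
  m <- specimen_metrics(cv)
  expect_equal(m$ultimate_stress_mpa, 75.8, tolerance = 0.2 / 75.8)
})

test_that("degenerate curves are rejected", {
  n <- 50
  monotone <- test_curve(1:n, seq(0, 5, length.out = n), seq(0, 100, length.out = n), csa = 10)
  expect_error(specimen_metrics(monotone), "no failure")
  flat <- test_curve(1:n, seq(0, 5, length.out = n), rep(0, n), csa = 10)
  expect_error(specimen_metrics(flat), "no failure|zero-force")
  expect_error(fit_initial_modulus(flat), "flat|zero")
})

test_that("group summary regenerates every mean and SD cell at printed rounding", {
  summ <- summarize_group(table1)
  # printed table: rows mean then SD for each metric x sub-tendon
  printed <- list(
    csa_mm2 = list(LG = c(9.3, 4.0), MG = c(13.4, 2.7), SOL = c(32.8, 7.6)),
    failure_force_n = list(LG = c(414.5, 242.5), MG = c(586.2, 111.3), SOL = c(1420.6, 277.1)),
    ultimate_stress_mpa = list(LG = c(53.4, 33.4), MG = c(45.1, 12.2), SOL = c(45.2, 10.4)),
    ultimate_strain_pct = list(LG = c(10.1, 1.6), MG = c(10.4, 1.2), SOL = c(14.7, 3.9)),
    modulus_mpa = list(LG = c(729.5, 449.5), MG = c(579.4, 149.9), SOL = c(480.3, 192.7)),
    stiffness_n_mm = list(LG = c(93.5, 43.5), MG = c(130.5, 20.9), SOL = c(263.9, 103.4)))
  for (met in names(printed)) {
    for (st in names(printed[[met]])) {
      row <- summ[summ$metric == met & summ$sub_tendon == st, ]
      expect_equal(round(row$mean, 1), printed[[met]][[st]][1],
                   info = paste(met, st, "mean"))
      expect_equal(round(row$sd, 1), printed[[met]][[st]][2],
                   info = paste(met, st, "sd"))
    }
  }
  expect_error(summarize_group(table1[table1$specimen == "69-M", ]), "at least 2")
})

test_that("Kruskal-Wallis H matches the hand-ranked oracle on CSA", {
  # ranks of the 15 CSA values give R = (19, 36, 65):
  # H = 12/(15*16) * sum(R^2/5) - 3*16 = 10.82
  kw <- kruskal_wallis(list(tab1_vals("csa_mm2", "LG"),
                            tab1_vals("csa_mm2", "MG"),
                            tab1_vals("csa_mm2", "SOL")))
  expect_equal(kw$statistic, 10.82, tolerance = 0.01 / 10.82)
  # independent route: stats::kruskal.test
  ref <- stats::kruskal.test(list(tab1_vals("csa_mm2", "LG"),
                                  tab1_vals("csa_mm2", "MG"),
                                  tab1_vals("csa_mm2", "SOL")))
  expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(kw$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis handles degenerate and separated groups", {
  same <- kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  sep <- kruskal_wallis(list(c(1, 2, 3), c(100, 101, 102)))
  expect_lt(sep$p_value, 0.05)
})

test_that("exact Mann-Whitney matches enumeration oracles", {
  # complete separation at n = 5 vs 5: U = 0, p = 2/252
  mw <- mann_whitney_exact(tab1_vals("csa_mm2", "LG"), tab1_vals("csa_mm2", "SOL"))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 2 / 252, tolerance = 1e-12)
  # C(4,2) = 6 arrangements
  mw2 <- mann_whitney_exact(c(1, 2), c(3, 4))
  expect_equal(mw2$statistic, 0)
  expect_equal(mw2$p_value, 2 / 6, tolerance = 1e-12)
  # ties, single values
  expect_equal(mann_whitney_exact(1, 1)$p_value, 1)
  expect_error(mann_whitney_exact(numeric(0), 1), "empty")
})

test_that("exact Mann-Whitney agrees with brute-force enumeration and wilcox.test", {
  set.seed(11)
  for (rep in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- round(rnorm(na), 2); b <- round(rnorm(nb, 0.5), 2)
    p_pkg <- mann_whitney_exact(a, b)$p_value
    # brute force over all C(na+nb, na) rank assignments
    r <- rank(c(a, b)); N <- na + nb
    sums <- colSums(matrix(r[utils::combn(N, na)], nrow = na))
    wa <- sum(r[seq_len(na)])
    p_bf <- min(1, 2 * min(mean(sums <= wa + 1e-9), mean(sums >= wa - 1e-9)))
    expect_equal(p_pkg, p_bf, tolerance = 1e-12, info = paste("rep", rep))
    if (!anyDuplicated(c(a, b)))
      expect_equal(p_pkg, stats::wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-10)
  }
})

test_that("post hoc stars reproduce the published pattern", {
  ph <- posthoc_vs_soleus(table1)
  starred <- c("csa_mm2", "failure_force_n", "stiffness_n_mm")
  for (m in unique(ph$metric)) {
    for (st in c("LG", "MG")) {
      hit <- ph$significant[ph$metric == m & ph$sub_tendon == st]
      expect_identical(hit, m %in% starred, label = paste(m, st))
    }
  }
  # every starred comparison is the complete-separation p = 2/252 < 0.017
  expect_true(all(abs(ph$p_value[ph$metric %in% starred] - 2 / 252) < 1e-12))
  # a stricter threshold extinguishes all flags
  ph2 <- posthoc_vs_soleus(table1, threshold = 0.001)
  expect_false(any(ph2$significant))
})

test_that("report driver assembles summary, omnibus and post hoc results", {
  rep <- run_invitro_report()
  expect_true(all(c("summary", "kruskal_wallis", "posthoc") %in% names(rep)))
  expect_equal(nrow(rep$kruskal_wallis), 6)
  st <- rep$summary
  expect_true(all(st$starred[st$metric == "csa_mm2" & st$sub_tendon %in% c("LG", "MG")]))
  expect_false(any(st$starred[st$metric == "ultimate_strain_pct" & st$sub_tendon %in% c("LG", "MG")]))
  expect_error(run_invitro_report(table1[table1$specimen == "69-M", ]), "at least 2")
  expect_warning(posthoc_vs_soleus(table1[table1$sub_tendon != "SOL", ]), "no soleus")
})

test_that("male/female combined means match the quoted subgroup values", {
  sx <- sex_subgroup_means(table1)
  # half a unit in the last printed digit absorbs the published rounding
  # (the male mean is exactly 62.05 from the printed per-specimen values)
  expect_equal(sx$combined_csa_mm2[sx$sex == "M"], 62.1, tolerance = 0.051 / 62.1)
  expect_equal(sx$combined_csa_mm2[sx$sex == "F"], 51.2, tolerance = 0.051 / 51.2)
  expect_equal(sx$combined_failure_force_n[sx$sex == "M"], 2478.1, tolerance = 0.051 / 2478.1)
  expect_equal(sx$combined_failure_force_n[sx$sex == "F"], 2383.5, tolerance = 0.051 / 2383.5)
})
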