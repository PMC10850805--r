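test_that("mutation_flag: hotspot/damaging define mutant; absent = unknown", {
  mut <- data.frame(
    line_id = c("L1", "L2", "L2", "L3"),
    gene = c("TP53", "TP53", "KRAS", "TP53"),
    variant_class = c("missense", "silent", "missense", "silent"),
    is_hotspot = c(TRUE, FALSE, FALSE, FALSE),
    is_damaging = c(FALSE, FALSE, TRUE, FALSE))
  fl <- mutation_flag(mut, "TP53", c("L1", "L2", "L3", "L4"))
  expect_equal(unname(fl), c("mutant", "wildtype", "wildtype", "unknown"))
  # flagged record on another gene does not leak
  expect_equal(unname(mutation_flag(mut, "KRAS", "L1")), "wildtype")
})

test_that("associate: hand-computable d, gates, label-swap antisymmetry", {
  eff <- c(A1 = -0.2, A2 = 0.0, A3 = -0.1, B1 = -1.0, B2 = -0.8, B3 = -0.9)
  flags <- c(A1 = "mutant", A2 = "mutant", A3 = "mutant",
             B1 = "wildtype", B2 = "wildtype", B3 = "wildtype")
  res <- associate(eff, flags)
  expect_equal(res$cohens_d, 8, tolerance = 1e-12)  # pooled SD 0.1, diff 0.8
  expect_equal(res$n_mutant, 3)
  expect_true(res$significant)

  swapped <- c(A1 = "wildtype", A2 = "wildtype", A3 = "wildtype",
               B1 = "mutant", B2 = "mutant", B3 = "mutant")
  res_sw <- associate(eff, swapped)
  expect_equal(res_sw$cohens_d, -res$cohens_d, tolerance = 1e-12)
  expect_equal(res_sw$t_statistic, -res$t_statistic, tolerance = 1e-12)
  expect_equal(res_sw$p_value, res$p_value, tolerance = 1e-12)

  ident <- c(eff[1:3], stats::setNames(eff[1:3], c("B1", "B2", "B3")))
  expect_equal(associate(ident, flags)$cohens_d, 0)
  expect_false(associate(ident, flags)$significant)

  expect_error(associate(eff, c(A1 = "mutant", B1 = "wildtype",
                                B2 = "wildtype")), "insufficient group")
  # unknown lines leave both groups
  fl_u <- flags; fl_u["A1"] <- "unknown"
  expect_equal(associate(eff, fl_u)$n_mutant, 2)
})

test_that("planted 1.5-SD shift at n = 10/10 is detected in most runs", {
  set.seed(47)
  hits <- replicate(200, {
    eff <- c(rnorm(10, -1.5, 1), rnorm(10, 0, 1))
    names(eff) <- sprintf("L%02d", 1:20)
    flags <- stats::setNames(rep(c("mutant", "wildtype"), each = 10),
                             names(eff))
    associate(eff, flags)$significant
  })
  expect_gte(mean(hits), 0.80)
})

test_that("association_screen: prevalence filter, grid size, planted recovery", {
  # shift -4 baseline SDs = -0.6 on the effect scale; against the planted
  # target's bimodal effect distribution (SD ~ 0.3) this is Cohen's d ~ -2
  pa <- data.frame(target_index = 2L, biomarker = "BM3", shift = -4)
  hits <- logical(10)
  for (s in 1:10) {
    b <- generate_panel(panel_config(n_lines = 87, n_genes = 200,
                                     n_druggable = 60,
                                     n_common_essential = 20,
                                     n_core_fitness = 15,
                                     exclusion_overlap = 10,
                                     n_druggable_excluded = 10,
                                     n_planted_targets = 5,
                                     n_lowfreq_targets = 5,
                                     planted_associations = pa, seed = s))
    scr <- association_screen(b$effect, b$truth$planted_targets,
                              names(b$config$biomarkers), b$mutations)
    expect_equal(nrow(scr), length(b$truth$planted_targets) *
                   length(names(b$config$biomarkers)))
    sig <- scr[scr$significant, ]
    hits[s] <- nrow(sig) == 1 &&
      sig$target == b$truth$planted_associations$target &&
      sig$biomarker == "BM3" && sig$cohens_d < 0
  }
  expect_gte(mean(hits), 0.8)   # planted pair recovered, nothing else

  # biomarker below 5% prevalence is excluded up front
  b <- generate_panel(small_cfg(seed = 1, biomarkers = c(BM1 = 0.5,
                                                         RARE1 = 0.02)))
  scr <- association_screen(b$effect, b$truth$planted_targets,
                            c("BM1", "RARE1"), b$mutations)
  expect_true("RARE1" %in% attr(scr, "excluded_biomarkers"))
  expect_false("RARE1" %in% scr$biomarker)
  expect_true(all(c("p_bh") %in% names(scr)))
})

test_that("dependency_covariate_correlation: exact lines and planted rho", {
  x <- stats::setNames(rnorm(5), letters[1:5])
  expect_equal(dependency_covariate_correlation(x, x)$statistic, 1)
  expect_equal(dependency_covariate_correlation(x, -x)$statistic, -1)
  # name-based join drops non-overlapping samples
  y <- stats::setNames(c(x[1:4], 99), c(letters[1:4], "zz"))
  expect_equal(dependency_covariate_correlation(x, y)$n, 4)

  set.seed(57)
  rs <- replicate(200, {
    z <- rnorm(50)
    x <- z
    y <- -0.6 * z + sqrt(1 - 0.36) * rnorm(50)
    dependency_covariate_correlation(x, y)$statistic
  })
  expect_equal(mean(rs), -0.6, tolerance = 0.05)
})

test_that("classify_gistic maps the 5-level code set and rejects others", {
  lv <- classify_gistic(-2:2)
  expect_equal(as.character(lv), c("deep_deletion", "loss", "diploid",
                                   "gain", "amplification"))
  expect_true(is.ordered(lv))
  expect_error(classify_gistic(3), "GISTIC")
  expect_true(is.na(classify_gistic(NA_integer_)))
})

test_that("coamplification: trivial fractions and planted amplicon rates", {
  calls <- rbind(c(2, 2, 0), c(2, 2, 1), c(1, 0, 0), c(0, 2, 2))
  dimnames(calls) <- list(sprintf("T%d", 1:4), c("ANCH", "P1", "P2"))
  co <- coamplification("ANCH", c("P1", "P2"), calls)
  expect_equal(co$n_anchor_amplified, rep(2L, 2))
  expect_equal(co$fraction, c(1.0, 0.0))  # P1 always, P2 never co-amplified

  co_gain <- coamplification("ANCH", "P1", calls, gain_counts = TRUE)
  expect_equal(co_gain$n_anchor_amplified, 3L)

  none <- calls; none[, "ANCH"] <- 0
  expect_error(coamplification("ANCH", "P1", none), "undefined")
  expect_error(coamplification("NOPE", "P1", calls), "absent")

  # planted cohort: co-amplification frequency ~ the planted rate, and the
  # result is invariant to tumour row order
  b <- generate_panel(small_cfg(seed = 9))
  calls_m <- gistic_matrix(b$tumours)
  co <- coamplification(b$truth$anchor, b$truth$amplicon_partners, calls_m)
  rate <- b$config$amplicon$partner_coamp_rate
  n <- co$n_anchor_amplified[1]
  expect_true(all(abs(co$fraction - rate) < 3 * sqrt(rate * (1 - rate) / n)))
  perm <- sample(nrow(calls_m))
  expect_equal(coamplification(b$truth$anchor, b$truth$amplicon_partners,
                               calls_m[perm, ]), co)
})

test_that("stratify_by_amplification: exact U path and group bookkeeping", {
  vals <- stats::setNames(c(1, 2, 3, 4, 5, 6), sprintf("S%d", 1:6))
  amp <- stats::setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                         names(vals))
  res <- stratify_by_amplification(vals, amp)
  expect_equal(res$test$statistic, 0)
  expect_equal(res$test$p_value, 0.1)   # enumeration over 20 labelings
  expect_equal(res$median_amplified, 2)

  ident <- stats::setNames(rep(c(1, 2, 3), 2), sprintf("S%d", 1:6))
  res_i <- stratify_by_amplification(ident, amp)  # ties -> normal path
  expect_equal(res_i$test$p_value, 1)

  vals48 <- stats::setNames(rnorm(48), sprintf("S%d", 1:48))
  amp48 <- stats::setNames(seq_len(48) <= 10, names(vals48))
  res48 <- stratify_by_amplification(vals48, amp48)
  expect_equal(res48$n_amplified, 10)
  expect_equal(res48$n_other, 38)
  expect_error(stratify_by_amplification(vals48[1:3], amp48[1:3]),
               "insufficient")
})

test_that("km_logrank: identical strata give chi-square 0; power at HR 2", {
  t0 <- c(5, 10, 15, 20, 25, 30)
  ev <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  res <- km_logrank(c(t0, t0), c(ev, ev), rep(c("a", "b"), each = 6))
  expect_equal(res$chisq, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1, tolerance = 1e-10)

  set.seed(67)
  null_rej <- replicate(200, {
    tt <- rexp(200, 0.05); cen <- pmin(tt, 40)
    km_logrank(cen, tt <= 40, rep(c("a", "b"), each = 100))$p_value < 0.05
  })
  expect_lt(abs(mean(null_rej) - 0.05), 0.04)

  pow <- replicate(100, {
    tt <- c(rexp(100, 0.05), rexp(100, 0.1))  # hazard ratio 2
    cen <- pmin(tt, 40)
    km_logrank(cen, tt <= 40, rep(c("a", "b"), each = 100))$p_value
  })
  expect_lt(median(pow), 0.05)

  expect_error(km_logrank(t0, ev, rep("a", 6)), ">= 2 strata")
})
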