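test_that("the training-split screen recovers planted markers with high AUC", {
  sim <- generate_dataset(simulation_design(seed = 8))
  planted <- unlist(sim$truth$blocks)
  s1 <- step1_screen(sim$dataset, config = quick_config(seed = 8))
  expect_gte(mean(planted %in% s1$selected), 0.9)
  # false positives stay rare among 598 null metabolites
  expect_lt(length(setdiff(s1$selected, planted)), 0.05 * 598)
  expect_gt(s1$auc$ci_lower, 0.9)
})

test_that("an impossible loading threshold empties the screen with a warning", {
  sim <- generate_dataset(simulation_design(seed = 9))
  cfg <- quick_config(seed = 9, loading_threshold = Inf)
  expect_warning(s1 <- step1_screen(sim$dataset, config = cfg),
                 "no metabolites")
  expect_length(s1$selected, 0)
  expect_null(s1$auc)
})

test_that("stability retention is strict at the threshold", {
  fractions <- c(keep = 0.96, drop_low = 0.94, drop_tie = 0.95)
  expect_identical(oplsage:::.stability_select(fractions, 0.95), "keep")
})

test_that("a perfect predictor is stable in every resampling round", {
  sig <- signal_matrix(n = 40, p = 8, noise = 0.05, seed = 3)
  st <- step2_vip_stability(sig$X, sig$y,
                            quick_config(seed = 3, n_bootstrap_vip = 100))
  expect_equal(unname(st$stability_fraction[1]), 1)
  expect_true("V1" %in% st$selected)
})

test_that("stability fractions are deterministic and threshold-monotone", {
  X <- null_matrix(30, 12, 17)
  y <- balanced_labels(30)
  cfg <- quick_config(seed = 17, n_bootstrap_vip = 60)
  a <- step2_vip_stability(X, y, cfg)
  b <- step2_vip_stability(X, y, cfg)
  expect_identical(a$stability_fraction, b$stability_fraction)

  loose <- oplsage:::.stability_select(a$stability_fraction, 0.5)
  tight <- oplsage:::.stability_select(a$stability_fraction, 0.9)
  expect_true(all(tight %in% loose))
})

test_that("PCA reduction applies the 0.9-max coefficient rule per component", {
  fb <- five_block_matrix(1)
  st3 <- step3_pca_reduce(fb$X, run_config())
  # the rule recomputed from the returned loadings
  for (cn in colnames(st3$loadings)) {
    cj <- st3$loadings[, cn]
    expect_setequal(st3$significant[[cn]],
                    names(which(abs(cj) > 0.9 * max(abs(cj)))))
    # the argmax itself is always significant
    expect_true(names(which.max(abs(cj))) %in% st3$significant[[cn]])
    # sign convention: the largest-magnitude coefficient is positive
    expect_gt(cj[which.max(abs(cj))], 0)
  }
  # minimality of the component count at the variance target
  cum <- cumsum(st3$variance_explained)
  expect_gte(cum[st3$n_components], 0.8 - 1e-12)
  if (st3$n_components > 1) expect_lt(cum[st3$n_components - 1], 0.8)
})

test_that("five planted blocks are recovered as five clean components", {
  pure <- vapply(1:20, function(s) {
    fb <- five_block_matrix(s)
    st3 <- step3_pca_reduce(fb$X, run_config())
    st3$n_components == 5 &&
      all(vapply(st3$significant, function(mem)
        length(unique(fb$block[match(mem, colnames(fb$X))])) == 1,
        logical(1)))
  }, logical(1))
  expect_gte(mean(pure), 0.9)
})

test_that("a full variance target saturates at the matrix rank", {
  X <- null_matrix(10, 6, 2)
  st3 <- step3_pca_reduce(X, run_config(pca_variance_target = 1))
  expect_equal(st3$n_components, qr(scale(X))$rank)
  expect_error(step3_pca_reduce(X[, 1, drop = FALSE], run_config()),
               "two metabolites")
})

test_that("the final intersection keeps step-2 metabolites with assignments", {
  loadings <- cbind(f1 = c(a = 0.9, b = 0.05, c = 0.3),
                    f2 = c(a = 0.1, b = 0.95, c = 0.4))
  step3 <- list(loadings = loadings,
                significant = list(f1 = c("a", "c"), f2 = c("b", "c")))
  final <- step4_intersect(c("a", "c"), step3)
  expect_setequal(final$metabolite, c("a", "c"))
  # b is significant in f2 but missing from step 2: excluded
  expect_false("b" %in% final$metabolite)
  expect_equal(final$component[final$metabolite == "a"], "f1")
  # c is significant in both; assigned to its larger coefficient (f2)
  expect_equal(final$component[final$metabolite == "c"], "f2")
  expect_equal(final$coefficient[final$metabolite == "c"], 0.4)
})

test_that("on null data the four-step selection returns almost nothing", {
  finals <- vapply(1:12, function(s) {
    sim <- generate_dataset(simulation_design(blocks = list(), seed = s))
    cfg <- quick_config(seed = s, n_bootstrap_model = 0,
                        n_bootstrap_vip = 150)
    sel <- suppressWarnings(
      select_metabolites(sim$dataset$concentrations,
                         encode_group(sim$dataset), cfg))
    nrow(sel$final)
  }, numeric(1))
  # a couple of dataset-level lucky metabolites can survive the stability
  # filter, but the selection never grows beyond a handful
  expect_true(all(finals <= 4))
  expect_gte(mean(finals == 0), 0.6)
  expect_lte(mean(finals), 1)
})

test_that("null stability fractions concentrate far below the retention cut", {
  sim <- generate_dataset(simulation_design(blocks = list(), seed = 4))
  st <- step2_vip_stability(sim$dataset$concentrations,
                            encode_group(sim$dataset),
                            quick_config(seed = 4, n_bootstrap_vip = 150))
  expect_lt(quantile(st$stability_fraction, 0.95), 0.8)
  expect_lt(mean(st$stability_fraction > 0.95), 0.01)
})

test_that("the selection trail is internally consistent", {
  sim <- generate_dataset(simulation_design(seed = 10))
  sel <- suppressWarnings(
    select_metabolites(sim$dataset$concentrations, encode_group(sim$dataset),
                       quick_config(seed = 10, n_bootstrap_vip = 150)))
  tr <- sel$trail
  expect_equal(nrow(tr), 628)
  expect_setequal(tr$metabolite[tr$final_selected], sel$final$metabolite)
  expect_true(all(tr$step2_selected[tr$final_selected]))
  expect_true(all(tr$stability_fraction >= 0 & tr$stability_fraction <= 1))
  # step 2 is a subset of step 1 within the pipeline wrapper
  expect_true(all(sel$step2$selected %in% sel$step1$selected))
})
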