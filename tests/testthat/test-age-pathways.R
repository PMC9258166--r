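test_that("Spearman correlation handles monotone, antitone and tied data", {
  expect_equal(spearman_cor(1:4, c(2, 4, 6, 8))$r, 1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(9, 3, 2, 1))$r, -1)

  # tied fixture: equals brute-force Pearson on mid-ranks
  x <- c(1, 2, 2, 3, 5, 5, 5, 8, 9, 9)
  y <- c(2, 1, 4, 4, 6, 7, 7, 7, 10, 9)
  got <- spearman_cor(x, y)
  expect_equal(got$r, cor(rank(x), rank(y)), tolerance = 1e-12)

  # agrees with the reference implementation (t-approximation branch)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)

  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:3, 1:3), "length")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(6)
  x <- rnorm(25)
  y <- 0.6 * x + rnorm(25)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$r, base$r, tolerance = 1e-12)
  expect_equal(spearman_cor(x, y^3 + 10)$r, base$r, tolerance = 1e-12)
})

test_that("the component screen applies the Bonferroni-corrected rule", {
  # craft a component whose within-case correlation is significant at the
  # unadjusted level but not after dividing alpha by five components
  set.seed(41)
  group <- rep(c("case", "control"), each = 16)
  age <- c(seq(60, 85, length.out = 16), seq(60, 85, length.out = 16))
  repeat {
    s1 <- scale(age[1:16])[, 1] * 0.62 + rnorm(16)
    sp <- spearman_cor(s1, age[1:16])
    if (sp$r > 0.5 && sp$p > 0.012 && sp$p < 0.045) break
  }
  scores5 <- cbind(f1 = c(s1, rnorm(16)),
                   f2 = rnorm(32), f3 = rnorm(32), f4 = rnorm(32),
                   f5 = rnorm(32))
  prof5 <- component_age_screen(scores5, group, age, run_config())
  expect_equal(prof5$classification[1], "neither")  # 0.05/5 threshold bites

  prof1 <- component_age_screen(scores5[, 1, drop = FALSE], group, age,
                                run_config())
  expect_equal(prof1$classification, "case-only")
  expect_equal(prof1$r_case, sp$r, tolerance = 1e-12)

  # a group below 4 subjects cannot be classified
  w <- capture_warnings(
    tiny <- component_age_screen(cbind(f1 = rnorm(6)),
                                 c("case", "case", "case", "control",
                                   "control", "control"),
                                 c(60, 65, 70, 62, 66, 71), run_config()))
  expect_true(any(grepl("fewer than 4", w)))
  expect_equal(tiny$classification, "neither")
})

test_that("null components are classified neither almost always", {
  cls <- vapply(1:100, function(s) {
    set.seed(s + 700)
    scores <- matrix(rnorm(78 * 3), 78, 3,
                     dimnames = list(NULL, paste0("f", 1:3)))
    prof <- component_age_screen(scores, rep(c("case", "control"), each = 39),
                                 rnorm(78, 72, 7), run_config())
    all(prof$classification == "neither")
  }, logical(1))
  expect_gte(mean(cls), 0.95)
})

test_that("metabolite-level age consistency follows the sign bookkeeping", {
  set.seed(51)
  n <- 30
  group <- rep(c("case", "control"), each = n)
  age <- c(runif(n, 60, 85), runif(n, 60, 85))
  case_rows <- which(group == "case")
  m1 <- numeric(2 * n)
  m1[case_rows] <- -0.1 * age[case_rows] + rnorm(n, 0, 0.3)
  m1[-case_rows] <- rnorm(n, -7, 1)
  m2 <- rnorm(2 * n)
  conc <- exp(cbind(m1 = m1 / 5, m2 = m2 / 5))
  rownames(conc) <- sprintf("S%02d", 1:(2 * n))
  ds <- metabolomics_dataset(conc, group, age)
  profiles <- data.frame(component = c("f1", "f2"),
                         r_case = c(-0.8, 0.05), p_case = c(1e-5, 0.8),
                         r_control = c(0.05, -0.1), p_control = c(0.7, 0.6),
                         n_case = n, n_control = n,
                         classification = c("case-only", "neither"),
                         stringsAsFactors = FALSE)

  # m1 loads positively on a case-only negatively-age-correlated component
  # and is itself negatively age-correlated in cases: consistent
  final <- data.frame(metabolite = c("m1", "m2"), component = c("f1", "f2"),
                      coefficient = c(0.6, 0.5), stringsAsFactors = FALSE)
  out <- verify_metabolite_age_consistency(final, ds, profiles, run_config())
  expect_true(out$consistent[out$metabolite == "m1"])
  # m2 sits on a neither component with no significant correlation
  expect_true(out$consistent[out$metabolite == "m2"])

  # flipping m1's coefficient sign breaks the expected direction
  final$coefficient[1] <- -0.6
  out2 <- verify_metabolite_age_consistency(final, ds, profiles, run_config())
  expect_false(out2$consistent[out2$metabolite == "m1"])
})

test_that("hypergeometric enrichment equals the exact combinatorial value", {
  universe <- paste0("M", 1:10)
  sets <- list(pathway_set("pw", universe[1:5]))
  res <- enrichment_ora(universe[1:4], universe, sets,
                        n_permutations = 200, seed = 1)
  expect_equal(res$p_hypergeometric, 5 / 210, tolerance = 1e-12)
  expect_equal(res$hits, 4L)
  expect_equal(res$enrichment_ratio, 4 / (4 * 5 / 10), tolerance = 1e-12)
})

test_that("permutation and hypergeometric enrichment P-values converge", {
  universe <- paste0("M", 1:10)
  sets <- list(pathway_set("pw", universe[1:5]))
  res <- enrichment_ora(universe[1:4], universe, sets,
                        n_permutations = 100000, seed = 2)
  expect_lt(abs(res$p_permutation - res$p_hypergeometric), 0.01)
})

test_that("enrichment validates inputs and skips empty pathways", {
  universe <- paste0("M", 1:10)
  expect_error(enrichment_ora(c("M1", "Z9"), universe,
                              list(pathway_set("pw", "M1"))), "subset")
  expect_warning(res <- enrichment_ora("M1", universe,
                                       list(pathway_set("out", c("X1", "X2")),
                                            pathway_set("in", "M1")),
                                       n_permutations = 100, seed = 1),
                 "no member")
  expect_equal(res$pathway, "in")
})

test_that("per-component enrichment recovers the planted pathways", {
  sim <- generate_dataset(simulation_design(seed = 12))
  ds <- sim$dataset
  cfg <- quick_config(seed = 12, n_bootstrap_vip = 200)
  sel <- suppressWarnings(select_metabolites(ds$concentrations,
                                             encode_group(ds), cfg))
  prof <- component_age_screen(sel$step3$scores, ds$group, ds$age, cfg)
  sets <- truth_pathway_sets(sim$truth, seed = 12)
  enr <- per_component_enrichment(sel, prof, sets, metabolite_ids(ds), cfg,
                                  seed = 12)
  expect_s3_class(enr$headline, "data.frame")
  # every populated component ranks a planted (non-decoy) pathway first
  expect_true(all(grepl("^pw_", enr$headline$top_pathway)))
  expect_true(all(enr$headline$p_permutation < 0.05))

  # destroying the membership structure destroys the significance
  planted <- unlist(sim$truth$blocks)
  top_query <- sel$final$metabolite[sel$final$component ==
                                      enr$headline$component[1]]
  null_sig <- vapply(1:20, function(s) {
    set.seed(s + 900)
    shuffled <- lapply(sets, function(ps)
      pathway_set(ps$name, sample(metabolite_ids(ds), length(ps$members))))
    res <- suppressWarnings(enrichment_ora(top_query, metabolite_ids(ds),
                                           shuffled, n_permutations = 400,
                                           seed = s))
    nrow(res) > 0 && min(res$p_permutation) <= 0.05
  }, logical(1))
  # small queries against size-16 shuffled sets can reach P ~ 0.05 by
  # chance in roughly one shuffle in eight; the structure-destroying
  # property is that the vast majority lose significance
  expect_lte(mean(null_sig), 0.25)
})
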