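test_that("matching rate arithmetic, symmetry and order invariance", {
  expect_equal(phenotype_matching_rate(c("+", "-", "+"), c("+", "+", "+")), 66.7)
  expect_equal(phenotype_matching_rate(c("+", "+"), c("+", "+")), 100.0)
  a <- c("+", "-", "+", "-", "+"); b <- c("+", "+", "-", "-", "+")
  expect_identical(phenotype_matching_rate(a, b), phenotype_matching_rate(b, a))
  ord <- sample(seq_along(a))
  expect_identical(phenotype_matching_rate(a[ord], b[ord]),
                   phenotype_matching_rate(a, b))
  expect_error(phenotype_matching_rate(c("+"), c("+", "-")), "differ in length")
  expect_error(phenotype_matching_rate("x", "+"), "invalid growth call")
  # typographic minus from transcribed tables is accepted
  expect_equal(phenotype_matching_rate(c("+", "−"), c("+", "-")), 100.0)
})

test_that("sole-source calls discriminate usable and dead substrates", {
  tm <- generate_toy_model(toy_model_spec(seed = 4))
  med <- tm$truth$media$minimal
  glc <- sole_source_call(tm$model, med, "EX_glc", "carbon")
  expect_identical(glc$call, "+")
  expect_equal(glc$growth_rate, tm$truth$analytic_max_growth, tolerance = 1e-6)
  # no inositol-utilizing reaction exists: negative call
  ino <- sole_source_call(tm$model, med, "EX_ino", "carbon")
  expect_identical(ino$call, "-")
  # substrate with an exchange but a gene-disabled catabolic route
  src <- setdiff(tm$truth$expected_phenotype_calls$substrate,
                 c("EX_glc", "EX_ino"))
  src <- src[grepl("^EX_(gal|man|fru|xyl|ara)", src)][1]
  cat_id <- paste0("CAT_", toupper(sub("EX_", "", src)))
  g <- gpr_genes(tm$model$reactions$gpr[tm$model$reactions$id == cat_id])
  dis <- tm$model
  j <- match(cat_id, dis$reactions$id)
  if (all(!evaluate_gpr(dis$reactions$gpr[j], g))) {
    dis$reactions$lower_bound[j] <- 0
    dis$reactions$upper_bound[j] <- 0
  }
  expect_identical(sole_source_call(dis, med, src, "carbon")$call, "-")
  # missing exchange is untestable, not negative
  unk <- sole_source_call(tm$model, med, "EX_sorbitol", "carbon")
  expect_identical(unk$call, "untestable")
  expect_true(is.na(unk$growth_rate))
})

test_that("nitrogen tests keep the carbon source and swap the nitrogen one", {
  tm <- generate_toy_model(toy_model_spec(seed = 4))
  med <- tm$truth$media$minimal
  expect_identical(sole_source_call(tm$model, med, "EX_nh4", "nitrogen")$call, "+")
  expect_identical(sole_source_call(tm$model, med, "EX_phe", "nitrogen")$call, "+")
  expect_identical(sole_source_call(tm$model, med, "EX_ure", "nitrogen")$call, "-")
  # without any nitrogen source there is no growth at all
  limits <- med$uptake_limits[setdiff(names(med$uptake_limits), "EX_nh4")]
  closed <- medium("noN", limits)
  sol <- solve_fba(apply_medium(tm$model, closed, ignore_missing = TRUE))
  expect_lt(sol$objective_value, 1e-9)
})

test_that("all planted phenotype calls are reproduced", {
  tm <- generate_toy_model(toy_model_spec(seed = 9))
  calls <- tm$truth$expected_phenotype_calls
  got <- vapply(seq_len(nrow(calls)), function(i) {
    sole_source_call(tm$model, tm$truth$media$minimal, calls$substrate[i],
                     calls$role[i])$call
  }, character(1))
  expect_identical(got, calls$call)
  expect_equal(phenotype_matching_rate(got, calls$call), 100.0)
})

test_that("supplementation increases are non-negative and routed supplements win", {
  tm <- generate_toy_model(toy_model_spec(seed = 2))
  scan <- supplementation_scan(tm$model, tm$truth$media$minimal,
                               c("EX_phe", "EX_ino"), uptake = 0.01)
  expect_identical(scan$status, rep("ok", 2))
  expect_true(all(scan$pct_increase_biomass >= -1e-6))
  expect_true(all(scan$pct_increase_eps >= -1e-6))
  phe <- scan[scan$supplement == "EX_phe", ]
  ino <- scan[scan$supplement == "EX_ino", ]
  expect_gt(phe$pct_increase_biomass, 0)   # feeds the amino-acid pool
  expect_equal(ino$pct_increase_biomass, 0, tolerance = 1e-6)  # no route in
  expect_equal(ino$pct_increase_eps, 0, tolerance = 1e-6)
  missing <- supplementation_scan(tm$model, tm$truth$media$minimal, "EX_gln")
  expect_identical(missing$status, "untestable")
})

test_that("a supplement's analytic yield gain is reproduced on a hand model", {
  # EPS needs X and Y 1:1; the carbon source makes both at cost 1 each;
  # supplement sxy delivers one X and one Y directly, supplement sx only X
  mets <- rbind(metabolite("c"), metabolite("x"), metabolite("y"),
                metabolite("sxy"), metabolite("sx"), metabolite("eps"))
  rxns <- list(
    reaction("EX_c", c(c = -1), lower_bound = -1, subsystem = "ER"),
    reaction("EX_sxy", c(sxy = -1), lower_bound = 0, subsystem = "ER"),
    reaction("EX_sx", c(sx = -1), lower_bound = 0, subsystem = "ER"),
    reaction("C2X", c(c = -1, x = 1)),
    reaction("C2Y", c(c = -1, y = 1)),
    reaction("SXY", c(sxy = -1, x = 1, y = 1)),
    reaction("SX", c(sx = -1, x = 1)),
    reaction("EPS", c(x = -1, y = -1, eps = 1)),
    reaction("EX_eps", c(eps = -1), subsystem = "ER"),
    reaction("BIOMASS", c(x = -1)))
  m <- metabolic_model(mets, rxns, "BIOMASS", eps_reaction_id = "EPS")
  med <- medium("min", c(EX_c = 1), carbon_source = "EX_c")
  scan <- supplementation_scan(m, med, c("EX_sxy", "EX_sx"), uptake = 0.1)
  # baseline EPS = 0.5 (two c per EPS unit); sxy adds a full unit -> 0.6;
  # sx only adds X while Y stays limiting -> 0.55
  expect_equal(scan$eps_rate[scan$supplement == "EX_sxy"], 0.6, tolerance = 1e-6)
  expect_equal(scan$eps_rate[scan$supplement == "EX_sx"], 0.55, tolerance = 1e-6)
  expect_equal(scan$pct_increase_eps[scan$supplement == "EX_sxy"], 20, tolerance = 1e-4)
  expect_equal(scan$pct_increase_eps[scan$supplement == "EX_sx"], 10, tolerance = 1e-4)
  # the dual-precursor supplement ranks first
  expect_identical(scan$supplement[1], "EX_sxy")
})
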