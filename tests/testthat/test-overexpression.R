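test_that("Eq.-1 style fold arithmetic is exact by construction", {
  rec <- overexpression_record("R", 2, V_biomass_wt = 1, V_biomass_oe = 1.2,
                               V_eps_wt = 1, V_eps_oe = 1.5)
  expect_equal(rec$f_biomass, 1.2)
  expect_equal(rec$f_eps, 1.5)
  expect_equal(rec$f_ph, 1.8)
  expect_identical(rec$f_ph, rec$f_biomass * rec$f_eps)
  # wild type against itself: all ratios one, never selected
  wt <- overexpression_record("R", 2, 1, 1, 0.5, 0.5)
  expect_equal(wt$f_ph, 1)
  expect_false(wt$selected)
  # the printed phosphomutase rates imply a 2.66-fold EPS increase
  pgm <- overexpression_record("PGM", 2, 1, 1, V_eps_wt = 0.005, V_eps_oe = 0.0133)
  expect_equal(pgm$f_eps, 2.66)
})

test_that("amplified bounds preserve flux direction", {
  m <- chain3_model()
  up <- overexpress_reaction(m, "R2", wt_flux = 2, fold = 2)
  expect_equal(up$reactions$lower_bound[up$reactions$id == "R2"], 4)
  mets <- rbind(metabolite("A"))
  mr <- metabolic_model(mets, list(
    reaction("REV", c(A = 1), lower_bound = -1000),
    reaction("BIOMASS", c(A = -1))), "BIOMASS")
  dn <- overexpress_reaction(mr, "REV", wt_flux = -3, fold = 2)
  expect_equal(dn$reactions$upper_bound[dn$reactions$id == "REV"], -6)
  expect_equal(dn$reactions$lower_bound[dn$reactions$id == "REV"], -1000)
  expect_error(overexpress_reaction(m, "R2", wt_flux = 0, fold = 2),
               "zero wild-type flux")
})

test_that("the screen follows the five steps and reports the planted target", {
  tm <- generate_toy_model(toy_model_spec(seed = 3))
  scr <- screen_targets(tm$model, tm$truth$media$fermentation)
  # step (i): the imposed product floor is phi times the EPS FBA maximum
  m_f <- apply_medium(tm$model, tm$truth$media$fermentation, ignore_missing = TRUE)
  eps_max <- solve_fba(m_f, "EPS")$objective_value
  expect_equal(attr(scr, "eps_imposed"), 0.1 * eps_max, tolerance = 1e-9)
  # step (iii): zero-flux reactions are skipped with a reason, not an error
  expect_true(any(scr$status == "skipped_zero_flux"))
  expect_false(any(scr$selected[scr$status != "optimal"]))
  # step (v): the top-ranked target is the planted one, selected with f_ph > 1
  expect_identical(scr$reaction[1], tm$truth$top_overexpression_target)
  expect_true(scr$selected[1])
  expect_gt(scr$f_ph[1], 1)
  expect_gt(scr$V_eps_oe[1], scr$V_eps_wt[1])
  # forcing flux on a unique EPS-branch step drags the whole sink up with it
  expect_true(scr$reaction[1] %in%
              c("PGM", "UGP", "GALE", "UGDH", "UXS", "UXE", "PMM", "GMP",
                "GFS", "RFFH", "RHS", "NDK_U", "NDK_G", "NDK_T", "PPA", "PGI", "PMI"))
  # gene mapping reports all isozymes behind a paired reaction
  gale <- scr[scr$reaction == "GALE", ]
  expect_identical(gale$genes, "gGALE_1,gGALE_2")
})

test_that("the screen is deterministic and stable under reaction reordering", {
  tm <- generate_toy_model(toy_model_spec(seed = 5))
  s1 <- screen_targets(tm$model, tm$truth$media$fermentation)
  s2 <- screen_targets(tm$model, tm$truth$media$fermentation)
  expect_identical(s1, s2)
  perm <- tm$model
  idx <- rev(seq_len(nrow(perm$reactions)))
  perm$reactions <- perm$reactions[idx, , drop = FALSE]
  rownames(perm$reactions) <- NULL
  perm$stoichiometry <- perm$stoichiometry[perm$reactions$id]
  s3 <- screen_targets(perm, tm$truth$media$fermentation)
  expect_setequal(s3$reaction[s3$selected], s1$reaction[s1$selected])
})

test_that("screen agrees with an explicit loop over all candidates", {
  # exhaustive cross-check at <= 10 reactions: apply each overexpression by
  # hand, run MOMA, and verify the screen's records match
  mets <- rbind(metabolite("s"), metabolite("x"), metabolite("e"))
  rxns <- list(
    reaction("EX_s", c(s = -1), lower_bound = -4, subsystem = "ER"),
    reaction("UP", c(s = -1, x = 1), gpr = "gup"),
    reaction("TOEPS", c(x = -1, e = 1), gpr = "geps"),
    reaction("EPS", c(e = -1)),
    reaction("BIOMASS", c(x = -1)))
  m <- metabolic_model(mets, rxns, "BIOMASS", eps_reaction_id = "EPS")
  med <- medium("min", c(EX_s = 4), carbon_source = "EX_s")
  scr <- screen_targets(m, med, fold = 2, phi = 0.1)
  mm <- apply_medium(m, med)
  eps_floor <- 0.1 * solve_fba(mm, "EPS")$objective_value
  mm <- set_reaction_bounds(mm, "EPS", lower_bound = eps_floor)
  ref <- parsimonious_reference(mm, "BIOMASS")
  for (rid in c("UP", "TOEPS")) {
    wt <- ref$fluxes[[rid]]
    row <- scr[scr$reaction == rid, ]
    if (abs(wt) <= 1e-6) {
      expect_identical(row$status, "skipped_zero_flux")
      next
    }
    sol <- solve_moma(overexpress_reaction(mm, rid, wt, 2), ref)
    if (sol$status != "optimal") {
      expect_identical(row$status, "infeasible")
      expect_true(is.na(row$V_eps_oe))
      next
    }
    expect_equal(row$V_eps_oe, sol$fluxes[["EPS"]], tolerance = 1e-7)
    expect_equal(row$V_biomass_oe, sol$fluxes[["BIOMASS"]], tolerance = 1e-7)
    expect_equal(row$f_ph, (sol$fluxes[["BIOMASS"]] / ref$fluxes[["BIOMASS"]]) *
                   (sol$fluxes[["EPS"]] / ref$fluxes[["EPS"]]), tolerance = 1e-7)
  }
  # TOEPS carries only the imposed floor; doubling it trades biomass for EPS
  toeps <- scr[scr$reaction == "TOEPS", ]
  expect_gt(toeps$f_eps, 1)
  expect_lt(toeps$f_biomass, 1)
})

test_that("infeasible amplifications are recorded, not raised", {
  # the uptake step already runs at the exchange cap: doubling is impossible
  mets <- rbind(metabolite("s"), metabolite("e"))
  rxns <- list(
    reaction("EX_s", c(s = -1), lower_bound = -4, upper_bound = 0, subsystem = "ER"),
    reaction("UP", c(s = -1, e = 1), upper_bound = 5),
    reaction("EPS", c(e = -1)),
    reaction("BIOMASS", c(e = -1)))
  m <- metabolic_model(mets, rxns, "BIOMASS", eps_reaction_id = "EPS")
  med <- medium("min", c(EX_s = 4), carbon_source = "EX_s",
                unconstrained_secretion = FALSE)
  scr <- screen_targets(m, med, fold = 2, phi = 0.5)
  up <- scr[scr$reaction == "UP", ]
  expect_identical(up$status, "infeasible")
  expect_false(up$selected)
})
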