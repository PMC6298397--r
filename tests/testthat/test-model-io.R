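test_that("equation parsing covers exchanges, coefficients and arrows", {
  ex <- parse_reaction_equation("glc-D[e] <=>")
  expect_equal(ex$stoichiometry, c(`glc-D[e]` = -1))
  expect_true(ex$reversible)
  rx <- parse_reaction_equation("A + 2 B -> C")
  expect_equal(rx$stoichiometry[c("A", "B", "C")], c(A = -1, B = -2, C = 1))
  expect_false(rx$reversible)
  expect_equal(parse_reaction_equation("0.5 X => Y")$stoichiometry[["X"]], -0.5)
  expect_error(parse_reaction_equation("A -- B"), "arrow token")
  expect_error(parse_reaction_equation("-2 A -> B"), "positive number")
})

write_tiny_table <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("reaction_id\tequation\tlower_bound\tupper_bound\tgpr\tsubsystem", rows),
             path)
  path
}

test_that("reaction tables parse into valid models", {
  path <- write_tiny_table(c(
    "R1\tglc-D[e] <=>\t-10\t1000\t\tER",
    "R2\tglc-D[e] + 2 B -> C\t0\t1000\tg1 and g2\tCM",
    "BIOMASS\tC ->\t0\t1000\t\tother"))
  m <- read_model_table(path)
  expect_s3_class(m, "metabolic_model")
  expect_equal(m$stoichiometry[["R1"]], c(`glc-D[e]` = -1))
  expect_true(is_exchange_reaction(m)[1])
  expect_equal(m$stoichiometry[["R2"]][c("glc-D[e]", "B", "C")],
               c(`glc-D[e]` = -1, B = -2, C = 1))
  expect_setequal(m$genes, c("g1", "g2"))
  expect_identical(m$metabolites$compartment[m$metabolites$id == "glc-D[e]"], "e")
  expect_false(evaluate_gpr(m$reactions$gpr[2], "g1"))
})

test_that("table reader reports duplicate ids and bad rows with row numbers", {
  path <- write_tiny_table(c("R1\tA -> B\t0\t1000\t\tCM",
                             "R1\tB ->\t0\t1000\t\tER"))
  expect_error(read_model_table(path), "duplicate reaction id 'R1' at row 2")
  path2 <- write_tiny_table(c("R1\tA >> B\t0\t1000\t\tCM",
                              "BIOMASS\tA ->\t0\t1000\t\tother"))
  expect_error(read_model_table(path2), "row 1 \\(R1\\)")
})

test_that("missing bounds default by reversibility", {
  path <- write_tiny_table(c("R1\tA <=> B\t\t\t\tCM",
                             "R2\tA -> B\t\t\t\tCM",
                             "BIOMASS\tB ->\t0\t1000\t\tother"))
  m <- read_model_table(path)
  expect_equal(m$reactions$lower_bound[1:2], c(-1000, 0))
  expect_equal(m$reactions$upper_bound[1:2], c(1000, 1000))
})

test_that("SBML round trip is the identity on all model fields", {
  tm <- generate_toy_model(toy_model_spec(seed = 8))
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(tm$model, path)
  back <- read_sbml(path)
  expect_identical(back$metabolites$id, tm$model$metabolites$id)
  expect_identical(back$metabolites$formula, tm$model$metabolites$formula)
  expect_identical(back$reactions$id, tm$model$reactions$id)
  expect_equal(back$reactions$lower_bound, tm$model$reactions$lower_bound)
  expect_equal(back$reactions$upper_bound, tm$model$reactions$upper_bound)
  expect_identical(back$reactions$subsystem, tm$model$reactions$subsystem)
  expect_identical(sort(back$genes), sort(tm$model$genes))
  expect_identical(back$biomass_reaction_id, tm$model$biomass_reaction_id)
  expect_identical(back$eps_reaction_id, tm$model$eps_reaction_id)
  for (rid in tm$model$reactions$id) {
    a <- tm$model$stoichiometry[[rid]]; b <- back$stoichiometry[[rid]]
    expect_equal(b[sort(names(b))], a[sort(names(a))], info = rid)
  }
})

test_that("awkward identifiers survive the SId encoding round trip", {
  mets <- rbind(metabolite("glc-D[e]", compartment = "e"), metabolite("13dpg"))
  rxns <- list(reaction("EX_glc(e)", c(`glc-D[e]` = -1), lower_bound = -10,
                        subsystem = "ER"),
               reaction("R 2", c(`glc-D[e]` = -1, `13dpg` = 1), gpr = "g-x or g.y"),
               reaction("BIOMASS", c(`13dpg` = -1)))
  m <- metabolic_model(mets, rxns, "BIOMASS")
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  back <- read_sbml(path)
  expect_identical(back$metabolites$id, m$metabolites$id)
  expect_identical(back$reactions$id, m$reactions$id)
  expect_setequal(back$genes, c("g-x", "g.y"))
})

test_that("GPR semantics survive SBML round trip on all knockout subsets", {
  mets <- rbind(metabolite("A"), metabolite("B"))
  rxns <- list(reaction("R1", c(A = 1), gpr = "(g1 and g2) or g3"),
               reaction("R2", c(A = -1, B = 1), gpr = ""),
               reaction("BIOMASS", c(B = -1)))
  m <- metabolic_model(mets, rxns, "BIOMASS")
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  back <- read_sbml(path)
  genes <- c("g1", "g2", "g3")
  for (mask in 0:7) {
    ko <- genes[bitwAnd(mask, c(1L, 2L, 4L)) > 0]
    expect_identical(evaluate_gpr(back$reactions$gpr[1], ko),
                     evaluate_gpr(m$reactions$gpr[1], ko))
  }
  expect_identical(back$reactions$gpr[2], "")   # no-association preserved
})

test_that("invalid SBML raises a parse error", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model></sbml>", path)
  expect_error(read_sbml(path), "cannot parse SBML")
  writeLines("<notsbml/>", path)
  expect_error(read_sbml(path), "no <model>")
})

test_that("table -> SBML -> table round trip is the identity on the dialect", {
  tm <- generate_toy_model(toy_model_spec(seed = 12, include_eps_pathway = FALSE))
  t1 <- withr::local_tempfile(fileext = ".tsv")
  x1 <- withr::local_tempfile(fileext = ".xml")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  write_model_table(tm$model, t1)
  m1 <- read_model_table(t1, biomass_reaction_id = "BIOMASS")
  write_sbml(m1, x1)
  write_model_table(read_sbml(x1), t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("medium presets encode the study media", {
  ferm <- load_medium("fermentation")
  aa_ex <- paste0("EX_", epsflux:::amino_acid_ids())
  expect_length(aa_ex, 20)
  expect_true(all(aa_ex %in% names(ferm$uptake_limits)))
  expect_equal(unname(ferm$uptake_limits[aa_ex]), rep(0.01, 20))
  minimal <- load_medium("minimal")
  expect_false(any(aa_ex %in% names(minimal$uptake_limits)))
  expect_equal(minimal$uptake_limits[["EX_glc"]], 10)
  custom <- load_medium(list(name = "glc-lim", base = "minimal",
                             uptake_limits = list(EX_glc = 0.506)))
  expect_equal(custom$uptake_limits[["EX_glc"]], 0.506)
  expect_error(load_medium("broth"), "unknown medium preset")
  expect_error(medium("bad", c(EX_glc = -1)), "negative uptake limit")
})

test_that("applying a medium opens listed uptakes and closes the rest", {
  tm <- generate_toy_model(toy_model_spec(seed = 1))
  m <- apply_medium(tm$model, tm$truth$media$fermentation)
  rx <- m$reactions
  expect_equal(rx$lower_bound[rx$id == "EX_glc"], -10)
  expect_equal(rx$lower_bound[rx$id == "EX_phe"], -0.01)
  expect_equal(rx$lower_bound[rx$id == "EX_ino"], 0)
  expect_equal(rx$lower_bound[rx$id == "HEX"], tm$model$reactions$lower_bound[
    tm$model$reactions$id == "HEX"])  # non-exchange untouched
  expect_error(apply_medium(tm$model, medium("bad", c(HEX = 1))),
               "not an exchange reaction")
  expect_error(apply_medium(tm$model, medium("bad", c(EX_nope = 1))),
               "not in the model")
  # opening an existing secretion exchange for uptake
  m2 <- apply_medium(tm$model, medium("auto", c(EX_pyr = 1, EX_glc = 10)))
  expect_equal(m2$reactions$lower_bound[m2$reactions$id == "EX_pyr"], -1)
  # auto-creation of a missing exchange for an existing metabolite when flagged
  m3 <- apply_medium(tm$model, medium("auto2", c(EX_aa = 0.5, EX_glc = 10)),
                     add_missing = TRUE)
  expect_true("EX_aa" %in% m3$reactions$id)
  expect_equal(m3$reactions$lower_bound[m3$reactions$id == "EX_aa"], -0.5)
})

test_that("empty medium closes all uptakes and growth collapses to zero", {
  tm <- generate_toy_model(toy_model_spec(seed = 1, include_eps_pathway = FALSE))
  m <- apply_medium(tm$model, medium("empty", stats::setNames(numeric(0), character(0))))
  sol <- solve_fba(m)
  expect_identical(sol$status, "optimal")
  expect_lt(abs(sol$objective_value), 1e-9)
})

test_that("FBA objective agrees with cobrapy on an SBML file we write", {
  tm <- generate_toy_model(toy_model_spec(seed = 6))
  m <- apply_medium(tm$model, tm$truth$media$minimal)
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  ours <- solve_fba(m)$objective_value
  script <- sprintf(
    "import cobra; m = cobra.io.read_sbml_model(%s); print(m.optimize().objective_value)",
    deparse(path))
  out <- tryCatch(system2("python", c("-c", shQuote(script)), stdout = TRUE,
                          stderr = FALSE),
                  warning = function(w) character(0), error = function(e) character(0))
  theirs <- suppressWarnings(as.numeric(out[length(out)]))
  expect_false(is.na(theirs))
  expect_equal(theirs, ours, tolerance = 1e-6)
})
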