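test_that("sole-path genes are essential, isozymes are not", {
  mets <- rbind(metabolite("A"), metabolite("B"))
  rxns <- list(
    reaction("EX_A", c(A = -1), lower_bound = -10),
    reaction("STEP", c(A = -1, B = 1), gpr = "gstep"),
    reaction("ISO", c(A = -1, B = 1), gpr = "iso1 or iso2"),
    reaction("BIOMASS", c(B = -1)))
  m <- metabolic_model(mets, rxns, "BIOMASS")
  del <- single_gene_deletion(m)
  expect_false(del$essential[del$gene == "gstep"])   # ISO still routes A -> B
  m2 <- metabolic_model(mets, rxns[-3], "BIOMASS")
  del2 <- single_gene_deletion(m2)
  expect_true(del2$essential[del2$gene == "gstep"])
  expect_identical(del2$disabled_reactions[del2$gene == "gstep"], "STEP")
  expect_false(any(del$essential[del$gene %in% c("iso1", "iso2")]))
})

test_that("genes outside every GPR leave the objective unchanged exactly", {
  tm <- generate_toy_model(toy_model_spec(seed = 5, include_eps_pathway = FALSE))
  m <- apply_medium(tm$model, tm$truth$media$minimal)
  wt <- solve_fba(m)$objective_value
  del <- single_gene_deletion(m, genes = c("ghost", tm$model$genes[1]))
  expect_identical(del$objective_value[del$gene == "ghost"], wt)
  expect_identical(del$disabled_reactions[del$gene == "ghost"], "")
})

test_that("planted essential genes are recovered exactly on both media", {
  for (seed in 0:4) {
    tm <- generate_toy_model(toy_model_spec(seed = seed))
    del_min <- single_gene_deletion(tm$model, tm$truth$media$minimal)
    expect_setequal(del_min$gene[del_min$essential], tm$truth$essential_genes_growth)
    del_ferm <- single_gene_deletion(tm$model, tm$truth$media$fermentation)
    expect_setequal(del_ferm$gene[del_ferm$essential],
                    tm$truth$essential_genes_growth_fermentation)
    # richer medium never enlarges the essential set
    expect_true(all(del_ferm$gene[del_ferm$essential] %in%
                    del_min$gene[del_min$essential]))
  }
})

test_that("the essential set is invariant to gene iteration order", {
  tm <- generate_toy_model(toy_model_spec(seed = 3, include_eps_pathway = FALSE))
  fwd <- single_gene_deletion(tm$model, tm$truth$media$minimal)
  rev <- single_gene_deletion(tm$model, tm$truth$media$minimal,
                              genes = base::rev(tm$model$genes))
  expect_setequal(fwd$gene[fwd$essential], rev$gene[rev$essential])
})

test_that("product essentiality separates the EPS branch from growth", {
  tm <- generate_toy_model(toy_model_spec(seed = 1))
  growth <- single_gene_deletion(tm$model, tm$truth$media$minimal)
  eps <- essential_for_product(tm$model, tm$truth$media$minimal)
  # the GDP-mannose pyrophosphorylase analogue: EPS-essential, growth-dispensable
  expect_true(eps$essential[eps$gene == "gGMP"])
  expect_false(growth$essential[growth$gene == "gGMP"])
  expect_setequal(eps$gene[eps$essential], tm$truth$essential_genes_eps)
  # every growth essential stays essential for the product under the floor
  expect_true(all(tm$truth$essential_genes_growth %in% eps$gene[eps$essential]))
})

test_that("biomass_fraction = 0 reduces to plain product essentiality", {
  tm <- generate_toy_model(toy_model_spec(seed = 1))
  eps0 <- essential_for_product(tm$model, tm$truth$media$minimal,
                                biomass_fraction = 0)
  # without the growth floor, a pure growth gene is dispensable for EPS
  expect_false(eps0$essential[eps0$gene == "gAAS"])
  expect_true(eps0$essential[eps0$gene == "gUGP"])
  expect_equal(attr(eps0, "biomass_floor"), 0)
})

test_that("deletion screens abort on an infeasible wild type", {
  m <- chain3_model()
  m <- set_reaction_bounds(m, "R3", lower_bound = 50)
  expect_error(single_gene_deletion(m), "wild-type FBA is infeasible")
})

test_that("subsystem percentages partition the essential set", {
  tm <- generate_toy_model(toy_model_spec(seed = 2))
  del <- single_gene_deletion(tm$model, tm$truth$media$minimal)
  pct <- subsystem_percentages(del, tm$model)
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  # hand count: gHK and gPFK sit on CM reactions, gAAS on AM, chain genes on CM
  n_ess <- sum(del$essential)
  expect_equal(pct[["AM"]], 100 / n_ess, tolerance = 1e-9)
  expect_equal(pct[["CM"]], 100 * (n_ess - 1) / n_ess, tolerance = 1e-9)
})

test_that("degenerate subsystem splits follow the documented conventions", {
  mets <- rbind(metabolite("A"), metabolite("B"), metabolite("C"))
  rxns <- list(
    reaction("EX_A", c(A = -1), lower_bound = -10, subsystem = "ER"),
    reaction("S1", c(A = -1, B = 1), gpr = "g1", subsystem = "LM"),
    reaction("S2", c(B = -1, C = 1), gpr = "g2", subsystem = "LM"),
    reaction("BIOMASS", c(C = -1)))
  m <- metabolic_model(mets, rxns, "BIOMASS")
  del <- single_gene_deletion(m)
  expect_equal(subsystem_percentages(del, m), c(LM = 100))
  # two essentials in two subsystems -> 50/50
  rxns[[3]] <- reaction("S2", c(B = -1, C = 1), gpr = "g2", subsystem = "AM")
  m2 <- metabolic_model(mets, rxns, "BIOMASS")
  del2 <- single_gene_deletion(m2)
  expect_equal(subsystem_percentages(del2, m2)[c("AM", "LM")], c(AM = 50, LM = 50))
  # a gene on subsystems {LM, LM, AM} is counted once, in LM (majority)
  rxns2 <- c(rxns[1:2], list(
    reaction("S1b", c(B = -1, C = 1), gpr = "g1", subsystem = "LM"),
    reaction("S1c", c(A = -1, C = 1), gpr = "g1", subsystem = "AM"),
    reaction("BIOMASS", c(C = -1))))
  m3 <- metabolic_model(mets, rxns2, "BIOMASS")
  del3 <- single_gene_deletion(m3)
  expect_equal(subsystem_percentages(del3, m3), c(LM = 100))
})
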