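#' Percent deviation of a predicted from an experimental rate
#'
#' `100 * (predicted - experimental) / experimental`, reported to one
#' decimal - the convention used when quoting growth-rate prediction
#' accuracy (e.g. a predicted 0.077 1/h against a measured 0.076 1/h is
#' "1.3% higher").
#'
#' @param predicted,experimental Rates in the same unit.
#' @return Signed percentage, rounded to one decimal.
#' @examples
#' percent_deviation(0.077, 0.076)  # 1.3
#' @export
percent_deviation <- function(predicted, experimental) {
  if (experimental == 0) stop("experimental rate must be non-zero", call. = FALSE)
  round(100 * (predicted - experimental) / experimental, 1)
}

#' Run the full analysis workflow on a model
#'
#' Orchestrates the validation and prediction arm of the study design:
#' model statistics and structural QC, sole-source phenotype calls against
#' supplied truth tables, the quantitative growth check under a measured
#' substrate-uptake constraint, single-gene essentiality for growth and for
#' EPS on both media, the amino-acid supplementation scan, and the MOMA
#' overexpression screen. Every number in the report is the direct output
#' of one exported operation; the report is deterministic for fixed inputs.
#'
#' @param model A `metabolic_model`, or a path to an SBML/TSV model file.
#' @param config A list of options:
#'   \describe{
#'     \item{media}{list with `minimal` and `fermentation`
#'       `medium_definition`s (default: presets, or [toy_media()] when the
#'       model uses the toy exchange convention).}
#'     \item{experimental_growth_rate}{Measured specific growth rate, 1/h
#'       (default 0.076).}
#'     \item{substrate_uptake}{Measured carbon-source uptake, mmol/gDW/h,
#'       imposed as the carbon cap for the quantitative check (default 0.506).}
#'     \item{phenotype_tables}{named list (`carbon`, `nitrogen`) of paths or
#'       data.frames with `substrate`, `in_vivo` columns; `in_silico` calls
#'       are recomputed and matched.}
#'     \item{biomass_fraction}{growth coupling for EPS essentiality (0.5).}
#'     \item{supplements}{exchange ids for the supplementation scan
#'       (default: the model's amino-acid exchanges).}
#'     \item{fold, phi}{overexpression screen parameters (2, 0.1).}
#'     \item{run_essentiality, run_supplementation, run_overexpression}{stage
#'       switches (all `TRUE`; EPS stages are skipped without an EPS
#'       reaction).}
#'   }
#' @return A list of class `eps_analysis_report` with sections
#'   `model_stats`, `qc`, `phenotypes`, `growth`, `essentiality`,
#'   `supplementation`, `overexpression`.
#' @export
run_full_analysis <- function(model, config = list()) {
  if (is.character(model)) {
    model <- if (grepl("\\.xml$", model)) read_sbml(model) else read_model_table(model)
  }
  validate_model(model)
  cfg <- utils::modifyList(list(
    media = NULL, experimental_growth_rate = 0.076, substrate_uptake = 0.506,
    phenotype_tables = NULL, biomass_fraction = 0.5, supplements = NULL,
    fold = 2, phi = 0.1, run_essentiality = TRUE, run_supplementation = TRUE,
    run_overexpression = TRUE), config)
  if (is.null(cfg$media)) {
    cfg$media <- if ("EX_glc" %in% model$reactions$id) toy_media(model) else
      list(minimal = load_medium("minimal"), fermentation = load_medium("fermentation"))
  }
  report <- list()
  ex <- is_exchange_reaction(model)
  sub_tab <- table(model$reactions$subsystem)
  report$model_stats <- list(
    genes = length(model$genes), metabolites = nrow(model$metabolites),
    reactions = nrow(model$reactions),
    gene_associated_reactions = sum(nzchar(model$reactions$gpr)),
    exchange_reactions = sum(ex),
    subsystem_percentages = round(100 * as.numeric(sub_tab) / nrow(model$reactions), 1) |>
      stats::setNames(names(sub_tab)))
  qc <- check_mass_charge_balance(model)
  report$qc <- list(balance = as.list(table(qc$status)),
                    imbalanced_reactions = qc$reaction_id[qc$status == "imbalanced"],
                    dead_ends = find_dead_ends(model))
  if (!is.null(cfg$phenotype_tables)) {
    report$phenotypes <- lapply(names(cfg$phenotype_tables), function(role) {
      tab <- cfg$phenotype_tables[[role]]
      if (is.character(tab)) tab <- read_phenotype_table(tab)
      calls <- vapply(tab$substrate, function(s) {
        ex_id <- if (grepl("^EX_", s)) s else paste0("EX_", s)
        sole_source_call(model, cfg$media$minimal, ex_id, role = role)$call
      }, character(1))
      list(role = role, substrates = tab$substrate, in_vivo = tab$in_vivo,
           in_silico = unname(calls),
           matching_rate = phenotype_matching_rate(
             tab$in_vivo, ifelse(calls == "untestable", "-", calls)))
    })
    names(report$phenotypes) <- names(cfg$phenotype_tables)
  }
  growth_medium <- cfg$media$minimal
  growth_medium$uptake_limits[[growth_medium$carbon_source]] <- cfg$substrate_uptake
  mu <- solve_fba(apply_medium(model, growth_medium, ignore_missing = TRUE),
                  model$biomass_reaction_id)
  report$growth <- list(
    substrate_uptake = cfg$substrate_uptake,
    predicted_growth_rate = mu$objective_value, status = mu$status,
    experimental_growth_rate = cfg$experimental_growth_rate,
    pct_deviation = if (mu$status == "optimal")
      percent_deviation(mu$objective_value, cfg$experimental_growth_rate) else NA_real_)
  if (isTRUE(cfg$run_essentiality)) {
    report$essentiality <- list()
    for (med in c("minimal", "fermentation")) {
      del <- single_gene_deletion(model, cfg$media[[med]],
                                  ignore_missing_exchanges = TRUE)
      entry <- list(objective = "growth", medium = med,
                    n_essential = sum(del$essential),
                    pct_of_genes = round(100 * sum(del$essential) / length(model$genes), 2),
                    essential_genes = del$gene[del$essential],
                    subsystem_percentages = round(subsystem_percentages(del, model), 2))
      report$essentiality[[paste0("growth_", med)]] <- entry
      if (!is.null(model$eps_reaction_id)) {
        dep <- essential_for_product(model, cfg$media[[med]],
                                     biomass_fraction = cfg$biomass_fraction,
                                     ignore_missing_exchanges = TRUE)
        report$essentiality[[paste0("eps_", med)]] <- list(
          objective = "eps", medium = med, n_essential = sum(dep$essential),
          pct_of_genes = round(100 * sum(dep$essential) / length(model$genes), 2),
          essential_genes = dep$gene[dep$essential],
          subsystem_percentages = round(subsystem_percentages(dep, model), 2))
      }
    }
  }
  if (isTRUE(cfg$run_supplementation) && !is.null(model$eps_reaction_id)) {
    supplements <- cfg$supplements
    if (is.null(supplements))
      supplements <- intersect(paste0("EX_", amino_acid_ids()), model$reactions$id)
    if (length(supplements)) {
      report$supplementation <- supplementation_scan(model, cfg$media$minimal,
                                                     supplements)
    }
  }
  if (isTRUE(cfg$run_overexpression) && !is.null(model$eps_reaction_id)) {
    report$overexpression <- screen_targets(model, cfg$media$fermentation,
                                            fold = cfg$fold, phi = cfg$phi)
  }
  structure(report, class = "eps_analysis_report")
}

#' @export
print.eps_analysis_report <- function(x, ...) {
  ms <- x$model_stats
  cat(sprintf("== model: %d genes | %d metabolites | %d reactions (%d gene-associated)\n",
              ms$genes, ms$metabolites, ms$reactions, ms$gene_associated_reactions))
  cat(sprintf("== QC: %s; dead ends: %s\n",
              paste(sprintf("%s %s", unlist(x$qc$balance), names(x$qc$balance)),
                    collapse = ", "),
              if (length(x$qc$dead_ends)) paste(x$qc$dead_ends, collapse = ", ") else "none"))
  for (ph in x$phenotypes)
    cat(sprintf("== phenotypes (%s): matching rate %.1f%% over %d substrates\n",
                ph$role, ph$matching_rate, length(ph$substrates)))
  g <- x$growth
  if (!is.null(g))
    cat(sprintf("== growth: predicted %.4g 1/h at uptake %.4g (experimental %.4g; deviation %+.1f%%)\n",
                g$predicted_growth_rate, g$substrate_uptake,
                g$experimental_growth_rate, g$pct_deviation))
  for (e in x$essentiality)
    cat(sprintf("== essential (%s, %s medium): %d genes (%.2f%%)\n",
                e$objective, e$medium, e$n_essential, e$pct_of_genes))
  if (!is.null(x$supplementation)) {
    top <- x$supplementation[1, ]
    cat(sprintf("== supplementation: best %s (+%.2f%% EPS)\n",
                top$supplement, top$pct_increase_eps))
  }
  if (!is.null(x$overexpression)) {
    sel <- x$overexpression[x$overexpression$selected, , drop = FALSE]
    cat(sprintf("== overexpression: %d selected target(s); top %s (f_PH %.3f)\n",
                nrow(sel), x$overexpression$reaction[1], x$overexpression$f_ph[1]))
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Raw values are retained; keys are emitted in a fixed order so repeated
#' runs on identical inputs are byte-identical.
#'
#' @param report An `eps_analysis_report`.
#' @param path Optional output path.
#' @return The JSON string, invisibly when writing to `path`.
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null", pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
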