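#' Parse a reaction equation string
#'
#' Dialect: whitespace-separated terms joined by `+` on each side of an
#' arrow token; `<=>` marks a reversible reaction, `->` / `=>` irreversible.
#' Coefficients are optional positive numbers (default 1); anything else in
#' a term is the metabolite id, which may carry a compartment suffix in
#' square brackets (`glc-D[e]`). One side may be empty (exchange/sink).
#'
#' @param equation Equation string, e.g. `"A + 2 B -> C"`.
#' @return List with `stoichiometry` (named numeric, substrates negative)
#'   and `reversible` (logical).
#' @export
parse_reaction_equation <- function(equation) {
  stopifnot(is.character(equation), length(equation) == 1)
  arrows <- c("<=>" = TRUE, "->" = FALSE, "=>" = FALSE)
  padded <- paste0(" ", gsub("\\s+", " ", trimws(equation)), " ")
  hit <- NULL
  for (a in names(arrows)) {
    if (grepl(paste0(" ", a, " "), padded, fixed = TRUE)) { hit <- a; break }
  }
  if (is.null(hit))
    stop(sprintf("unknown or missing arrow token in equation '%s' (use <=>, -> or =>)",
                 equation), call. = FALSE)
  sides <- strsplit(padded, paste0(" ", hit, " "), fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  lhs <- parse_equation_side(sides[1], equation)
  rhs <- parse_equation_side(sides[2], equation)
  st <- numeric(0)
  for (m in names(lhs)) st[m] <- (if (m %in% names(st)) st[m] else 0) - lhs[[m]]
  for (m in names(rhs)) st[m] <- (if (m %in% names(st)) st[m] else 0) + rhs[[m]]
  st <- st[abs(st) > 0]  # both-sides metabolites with equal coefficients cancel
  if (length(st) == 0)
    stop(sprintf("equation '%s' has empty net stoichiometry", equation), call. = FALSE)
  list(stoichiometry = st, reversible = unname(arrows[hit]))
}

parse_equation_side <- function(side, equation) {
  side <- trimws(side)
  if (!nzchar(side)) return(stats::setNames(numeric(0), character(0)))
  terms <- strsplit(side, "\\s\\+\\s|^\\+\\s|\\s\\+$")[[1]]
  terms <- trimws(terms[nzchar(trimws(terms))])
  out <- numeric(0)
  for (tm in terms) {
    toks <- strsplit(tm, "\\s+")[[1]]
    coef <- suppressWarnings(as.numeric(toks[1]))
    if (!is.na(coef) && length(toks) >= 2) {
      if (coef <= 0)
        stop(sprintf("coefficient must be a positive number in term '%s' of '%s'",
                     tm, equation), call. = FALSE)
      met <- paste(toks[-1], collapse = " ")
    } else {
      coef <- 1
      met <- paste(toks, collapse = " ")
    }
    out[met] <- (if (met %in% names(out)) out[[met]] else 0) + coef
  }
  out
}

#' Read a metabolic model from a tab-delimited reaction table
#'
#' Mirrors the layout of supplementary reaction-list tables: one row per
#' reaction with an equation string. Required columns (rename via
#' `col_map`): `reaction_id`, `equation`, `lower_bound`, `upper_bound`,
#' `gpr`, `subsystem`; an optional `name` column is honoured. Missing
#' bounds default to `[0, 1000]` for irreversible and `[-1000, 1000]` for
#' reversible equations. Metabolite compartments are read from a trailing
#' `[x]` suffix on the id. Formulas/charges can be supplied through an
#' optional metabolite table (`id`, plus any of `name`, `compartment`,
#' `formula`, `charge`).
#'
#' @param path Path to the tab-delimited reaction table (UTF-8, header row).
#' @param biomass_reaction_id Biomass reaction id; by default the first id
#'   matching `"biomass"` (case-insensitive).
#' @param eps_reaction_id Optional EPS sink id; by default the first id
#'   matching `"^EPS$|eps_sink"` (case-insensitive), if any.
#' @param col_map Named character vector mapping required column names to
#'   the file's actual headers, e.g. `c(reaction_id = "Rxn name")`.
#' @param metabolite_table Optional path or `data.frame` with metabolite
#'   annotations.
#' @param default_cap Absolute bound used when a bound cell is empty/NA.
#' @return A `metabolic_model`.
#' @export
read_model_table <- function(path, biomass_reaction_id = NULL, eps_reaction_id = NULL,
                             col_map = character(0), metabolite_table = NULL,
                             default_cap = 1000) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "", comment.char = "",
                           colClasses = "character")
  required <- c("reaction_id", "equation", "lower_bound", "upper_bound", "gpr", "subsystem")
  for (col in required) {
    src <- if (col %in% names(col_map)) col_map[[col]] else col
    if (!src %in% names(tab))
      stop(sprintf("missing column '%s' in %s", src, path), call. = FALSE)
    if (src != col) names(tab)[names(tab) == src] <- col
  }
  if (anyDuplicated(tab$reaction_id)) {
    dup <- which(duplicated(tab$reaction_id))[1]
    stop(sprintf("duplicate reaction id '%s' at row %d", tab$reaction_id[dup], dup),
         call. = FALSE)
  }
  rxns <- vector("list", nrow(tab))
  met_ids <- character(0)
  for (i in seq_len(nrow(tab))) {
    eq <- tryCatch(parse_reaction_equation(tab$equation[i]), error = function(e) {
      stop(sprintf("row %d (%s): %s", i, tab$reaction_id[i], conditionMessage(e)),
           call. = FALSE)
    })
    lb <- suppressWarnings(as.numeric(tab$lower_bound[i]))
    ub <- suppressWarnings(as.numeric(tab$upper_bound[i]))
    if (is.na(lb)) lb <- if (eq$reversible) -default_cap else 0
    if (is.na(ub)) ub <- default_cap
    rxns[[i]] <- reaction(
      id = tab$reaction_id[i], stoichiometry = eq$stoichiometry,
      name = if ("name" %in% names(tab)) tab$name[i] else tab$reaction_id[i],
      lower_bound = lb, upper_bound = ub,
      gpr = if (is.na(tab$gpr[i])) "" else tab$gpr[i],
      subsystem = if (is.na(tab$subsystem[i]) || !nzchar(tab$subsystem[i])) "other" else tab$subsystem[i])
    met_ids <- union(met_ids, names(eq$stoichiometry))
  }
  mets <- data.frame(id = met_ids,
                     name = met_ids,
                     compartment = ifelse(grepl("\\[[^]]+\\]$", met_ids),
                                          sub("^.*\\[([^]]+)\\]$", "\\1", met_ids), "c"),
                     formula = NA_character_, charge = NA_integer_,
                     stringsAsFactors = FALSE)
  if (!is.null(metabolite_table)) {
    ann <- if (is.data.frame(metabolite_table)) metabolite_table else
      utils::read.delim(metabolite_table, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE, quote = "")
    idx <- match(mets$id, ann$id)
    for (col in intersect(c("name", "compartment", "formula"), names(ann)))
      mets[[col]] <- ifelse(is.na(idx), mets[[col]], as.character(ann[[col]][idx]))
    if ("charge" %in% names(ann))
      mets$charge <- ifelse(is.na(idx), mets$charge, as.integer(ann$charge[idx]))
  }
  ids <- vapply(rxns, `[[`, character(1), "id")
  if (is.null(biomass_reaction_id)) {
    hit <- grep("biomass", ids, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0)
      stop("no biomass reaction found; pass biomass_reaction_id", call. = FALSE)
    biomass_reaction_id <- hit[1]
  }
  if (is.null(eps_reaction_id)) {
    hit <- grep("^EPS$|eps_sink", ids, ignore.case = TRUE, value = TRUE)
    eps_reaction_id <- if (length(hit)) hit[1] else NULL
  }
  metabolic_model(mets, rxns, biomass_reaction_id = biomass_reaction_id,
                  eps_reaction_id = eps_reaction_id,
                  id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a metabolic model as a tab-delimited reaction table
#'
#' Inverse of [read_model_table()]: equations are rendered with `<=>` for
#' reversible (`lower_bound < 0`) and `->` otherwise.
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_table <- function(model, path) {
  validate_model(model)
  eqs <- vapply(model$reactions$id, function(rid) {
    st <- model$stoichiometry[[rid]]
    rev <- model$reactions$lower_bound[match(rid, model$reactions$id)] < 0
    fmt <- function(v) paste(vapply(names(v), function(m) {
      if (abs(v[[m]] - 1) < 1e-12) m else paste(format(abs(v[[m]]), scientific = FALSE), m)
    }, character(1)), collapse = " + ")
    lhs <- fmt(abs(st[st < 0]))
    rhs <- fmt(st[st > 0])
    trimws(paste(lhs, if (rev) "<=>" else "->", rhs))
  }, character(1))
  out <- data.frame(reaction_id = model$reactions$id, name = model$reactions$name,
                    equation = eqs, lower_bound = model$reactions$lower_bound,
                    upper_bound = model$reactions$upper_bound,
                    gpr = model$reactions$gpr, subsystem = model$reactions$subsystem,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
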