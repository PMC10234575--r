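#' Construct a genome-scale metabolic model
#'
#' Holds metabolites, reactions (stoichiometry, bounds, gene-protein-reaction
#' rules, subsystem), genes, and a single biomass/objective reaction. The
#' stoichiometric matrix S is stored dense (metabolites x reactions), which is
#' appropriate for the curated, moderately sized networks this package
#' simulates.
#'
#' @param metabolites data.frame with `id` and optional `name`, `compartment`.
#' @param reactions data.frame with `id` and optional `name`, `lower_bound`,
#'   `upper_bound` (defaults 0 / 1000), `gpr` (boolean gene expression, "" for
#'   none), `subsystem`.
#' @param S numeric matrix, `nrow(metabolites)` x `nrow(reactions)`;
#'   dimnames are set from the ids.
#' @param objective id of the objective (biomass) reaction.
#' @param genes optional character vector of gene ids; defaults to the
#'   identifiers appearing in the GPR rules.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, S, objective, genes = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$lower_bound)) reactions$lower_bound <- 0
  if (is.null(reactions$upper_bound)) reactions$upper_bound <- 1000
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  S <- as.matrix(S)
  if (nrow(S) != nrow(metabolites) || ncol(S) != nrow(reactions)) {
    stop("S dimensions do not match metabolites x reactions")
  }
  dimnames(S) <- list(metabolites$id, reactions$id)
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")
  if (length(objective) != 1 || !objective %in% reactions$id) {
    stop("model needs exactly one objective reaction present in the network")
  }
  if (any(reactions$lower_bound > reactions$upper_bound)) {
    stop("reaction with lower_bound > upper_bound")
  }
  reactions$is_exchange <- colSums(S != 0) == 1
  if (is.null(genes)) genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  model <- structure(list(metabolites = metabolites, reactions = reactions,
                          S = S, objective = objective,
                          genes = as.character(genes)),
                     class = "metabolic_model")
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites, %d reactions (%d exchanges), %d genes\n",
              nrow(x$metabolites), nrow(x$reactions),
              sum(x$reactions$is_exchange), length(x$genes)))
  cat("  objective:", x$objective, "\n")
  invisible(x)
}

#' Extract the gene identifiers of a GPR rule
#'
#' @param gpr boolean gene-protein-reaction expression, e.g.
#'   `"(g1 and g2) or g3"`.
#' @return character vector of gene ids (empty for an empty rule).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr) || is.na(gpr) || !nzchar(trimws(gpr))) return(character(0))
  toks <- strsplit(gsub("[()]", " ", gpr), "\\s+")[[1]]
  setdiff(toks[nzchar(toks)], c("and", "or", "AND", "OR"))
}

# recursive-descent parse of a GPR boolean expression into nested lists
# list(op = "and"/"or"/"gene", args/gene)
.gpr_parse <- function(gpr) {
  toks <- regmatches(gpr, gregexpr("\\(|\\)|[^()\\s]+", gpr, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_expr <- function() {
    left <- parse_term()
    args <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance(); args <- c(args, list(parse_term()))
    }
    if (length(args) == 1) left else list(op = "or", args = args)
  }
  parse_term <- function() {
    left <- parse_factor()
    args <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance(); args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1) left else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- advance()
    if (identical(t, "(")) {
      e <- parse_expr()
      if (!identical(advance(), ")")) stop("unbalanced parentheses in GPR: ", gpr)
      e
    } else {
      list(op = "gene", gene = t)
    }
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("trailing tokens in GPR: ", gpr)
  out
}

.gpr_deparse <- function(node) {
  if (node$op == "gene") return(node$gene)
  inner <- vapply(node$args, function(a) {
    s <- .gpr_deparse(a)
    if (a$op %in% c("and", "or")) paste0("(", s, ")") else s
  }, character(1))
  paste(inner, collapse = paste0(" ", node$op, " "))
}

#' Read a metabolic model from SBML (Level 3 + FBC) or JSON
#'
#' The JSON dialect mirrors the common constraint-based exchange schema:
#' top-level arrays `metabolites` (id, name, compartment), `reactions` (id,
#' name, metabolites mapping, lower_bound, upper_bound, gene_reaction_rule,
#' subsystem, objective_coefficient), and `genes` (id). SBML input covers the
#' FBC subset needed here: species, reactions with flux-bound parameters,
#' gene-product associations, and the active objective.
#'
#' @param path model file.
#' @param dialect "json" or "sbml-fbc"; inferred from the extension when
#'   missing.
#' @return a [metabolic_model()].
#' @export
read_metabolic_model <- function(path, dialect = c("auto", "json", "sbml-fbc")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml-fbc"
  }
  if (dialect == "json") .read_model_json(path) else .read_model_sbml(path)
}

.read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(x$metabolites, function(m) {
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c", stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(x$reactions, function(r) {
    data.frame(id = r$id, name = r$name %||% r$id,
               lower_bound = r$lower_bound %||% 0,
               upper_bound = r$upper_bound %||% 1000,
               gpr = r$gene_reaction_rule %||% "",
               subsystem = r$subsystem %||% "", stringsAsFactors = FALSE)
  }))
  S <- matrix(0, nrow(mets), nrow(rxns), dimnames = list(mets$id, rxns$id))
  for (k in seq_along(x$reactions)) {
    st <- x$reactions[[k]]$metabolites
    bad <- setdiff(names(st), mets$id)
    if (length(bad)) {
      stop("reaction ", rxns$id[k], " references unknown metabolite(s): ",
           paste(bad, collapse = ", "))
    }
    for (m in names(st)) S[m, k] <- as.numeric(st[[m]])
  }
  objcoef <- vapply(x$reactions, function(r) r$objective_coefficient %||% 0, numeric(1))
  if (sum(objcoef != 0) != 1) stop("model must declare exactly one objective reaction")
  genes <- vapply(x$genes, function(g) g$id, character(1))
  metabolic_model(mets, rxns, S, objective = rxns$id[objcoef != 0],
                  genes = if (length(genes)) genes else NULL)
}

#' Write a metabolic model to JSON or SBML (Level 3 + FBC)
#'
#' @param model a [metabolic_model()].
#' @param path output file.
#' @param dialect "json" or "sbml-fbc"; inferred from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_metabolic_model <- function(model, path,
                                  dialect = c("auto", "json", "sbml-fbc")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml-fbc"
  }
  if (dialect == "json") .write_model_json(model, path) else .write_model_sbml(model, path)
  invisible(path)
}

.write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment)
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(k) {
    r <- model$reactions[k, ]
    st <- model$S[, k]
    st <- st[st != 0]
    list(id = r$id, name = r$name, metabolites = as.list(st),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gene_reaction_rule = r$gpr, subsystem = r$subsystem,
         objective_coefficient = if (r$id == model$objective) 1 else 0)
  })
  genes <- lapply(model$genes, function(g) list(id = g))
  jsonlite::write_json(list(metabolites = mets, reactions = rxns, genes = genes),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.sbml_ns <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"
)

.gpr_to_xml <- function(node, parent) {
  if (node$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef", "fbc:geneProduct" = node$gene)
  } else {
    el <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
    for (a in node$args) .gpr_to_xml(a, el)
  }
}

.write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = .sbml_ns[["sbml"]], "xmlns:fbc" = .sbml_ns[["fbc"]],
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model", "fbc:strict" = "true")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in unique(model$metabolites$compartment)) {
    xml2::xml_add_child(comps, "compartment", id = cp, constant = "true")
  }
  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(sp, "species", id = m$id, name = m$name,
                        compartment = m$compartment, constant = "false",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false")
  }
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  bounds <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  bid <- function(v) paste0("bnd_", gsub("[^0-9A-Za-z]", "_", format(v, digits = 15)))
  for (v in bounds) {
    xml2::xml_add_child(pars, "parameter", id = bid(v),
                        value = format(v, digits = 15), constant = "true")
  }
  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (k in seq_len(nrow(model$reactions))) {
    r <- model$reactions[k, ]
    rx <- xml2::xml_add_child(
      rl, "reaction", id = r$id, name = r$name, reversible = "true",
      fast = "false",
      "fbc:lowerFluxBound" = bid(r$lower_bound),
      "fbc:upperFluxBound" = bid(r$upper_bound))
    st <- model$S[, k]
    rea <- which(st < 0); pro <- which(st > 0)
    if (length(rea)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in rea) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = model$metabolites$id[i],
                            stoichiometry = format(-st[i], digits = 15),
                            constant = "true")
      }
    }
    if (length(pro)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in pro) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = model$metabolites$id[i],
                            stoichiometry = format(st[i], digits = 15),
                            constant = "true")
      }
    }
    if (nzchar(r$gpr)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      .gpr_to_xml(.gpr_parse(r$gpr), gpa)
    }
    if (nzchar(r$subsystem)) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
    }
  }
  obj <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  o1 <- xml2::xml_add_child(obj, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(o1, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective", "fbc:reaction" = model$objective,
                      "fbc:coefficient" = "1")
  gps <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model$genes) {
    xml2::xml_add_child(gps, "fbc:geneProduct", "fbc:id" = g, "fbc:label" = g)
  }
  xml2::write_xml(doc, path)
}

.xml_gpr_from_node <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    return(list(op = "gene", gene = xml2::xml_attr(node, "geneProduct")))
  }
  kids <- xml2::xml_children(node)
  list(op = nm, args = lapply(kids, .xml_gpr_from_node))
}

.read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  sp <- xml2::xml_find_all(doc, ".//sbml:listOfSpecies/sbml:species", ns)
  mets <- data.frame(id = xml2::xml_attr(sp, "id"),
                     name = xml2::xml_attr(sp, "name"),
                     compartment = xml2::xml_attr(sp, "compartment"),
                     stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  pars <- xml2::xml_find_all(doc, ".//sbml:listOfParameters/sbml:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  rxn_nodes <- xml2::xml_find_all(doc, ".//sbml:listOfReactions/sbml:reaction", ns)
  n_r <- length(rxn_nodes)
  rxns <- data.frame(id = xml2::xml_attr(rxn_nodes, "id"),
                     name = xml2::xml_attr(rxn_nodes, "name"),
                     lower_bound = pval[xml2::xml_attr(rxn_nodes, "lowerFluxBound")],
                     upper_bound = pval[xml2::xml_attr(rxn_nodes, "upperFluxBound")],
                     gpr = "", subsystem = "", stringsAsFactors = FALSE)
  rxns$name[is.na(rxns$name)] <- rxns$id[is.na(rxns$name)]
  S <- matrix(0, nrow(mets), n_r, dimnames = list(mets$id, rxns$id))
  for (k in seq_len(n_r)) {
    rn <- rxn_nodes[[k]]
    for (sr in xml2::xml_find_all(rn, "./sbml:listOfReactants/sbml:speciesReference", ns)) {
      m <- xml2::xml_attr(sr, "species")
      if (!m %in% mets$id) stop("reaction ", rxns$id[k], " references unknown metabolite ", m)
      S[m, k] <- S[m, k] - as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rn, "./sbml:listOfProducts/sbml:speciesReference", ns)) {
      m <- xml2::xml_attr(sr, "species")
      if (!m %in% mets$id) stop("reaction ", rxns$id[k], " references unknown metabolite ", m)
      S[m, k] <- S[m, k] + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    gpa <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation/*", ns)
    if (!inherits(gpa, "xml_missing")) {
      rxns$gpr[k] <- .gpr_deparse(.xml_gpr_from_node(gpa))
    }
    note <- xml2::xml_find_first(rn, ".//sbml:notes//*[starts-with(text(), 'SUBSYSTEM: ')]", ns)
    if (!inherits(note, "xml_missing")) {
      rxns$subsystem[k] <- sub("^SUBSYSTEM: ", "", xml2::xml_text(note))
    }
  }
  fo <- xml2::xml_find_first(doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(fo, "xml_missing")) stop("SBML model has no flux objective")
  objective <- xml2::xml_attr(fo, "reaction")
  gp <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  genes <- xml2::xml_attr(gp, "id")
  metabolic_model(mets, rxns, S, objective = objective,
                  genes = if (length(genes)) genes else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
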