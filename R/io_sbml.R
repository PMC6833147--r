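SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_V2_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
FBC_V1_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version1"

# Reversible SId sanitisation: invalid characters are escaped as __xHHHH__
# (4-digit hex codepoint); an id starting with a non-letter gets a __n__
# prefix. Decoding strips both. Ids that are already valid SIds pass through.
sid_encode <- function(id) {
  vapply(id, function(x) {
    chars <- strsplit(x, "")[[1]]
    enc <- vapply(chars, function(ch) {
      if (grepl("^[A-Za-z0-9_]$", ch)) ch
      else sprintf("__x%04X__", utf8ToInt(ch))
    }, character(1))
    out <- paste(enc, collapse = "")
    if (grepl("^[0-9]", out)) out <- paste0("__n__", out)
    out
  }, character(1), USE.NAMES = FALSE)
}

sid_decode <- function(id) {
  vapply(id, function(x) {
    x <- sub("^__n__", "", x)
    m <- gregexpr("__x([0-9A-Fa-f]{4})__", x)
    regmatches(x, m) <- lapply(regmatches(x, m), function(hits) {
      vapply(hits, function(h) intToUtf8(strtoi(substr(h, 4, 7), 16L)), character(1))
    })
    x
  }, character(1), USE.NAMES = FALSE)
}

#' Write a model as SBML Level 3 + FBC version 2
#'
#' Flux bounds are emitted as shared global parameters referenced by
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound`, GPRs as
#' `fbc:geneProductAssociation` trees, the objective as the active FBC
#' objective, metabolite formula/charge as FBC attributes, exchange status
#' as SBO:0000627, subsystems and maintenance parameters in notes. Entity
#' ids get the conventional `M_`/`R_`/`G_` prefixes plus reversible escaping
#' of non-SId characters, so [read_sbml()] reproduces the model exactly.
#'
#' @param model a `gem`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_CORE_NS, "xmlns:fbc" = FBC_V2_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sid_encode(model$id),
                             "fbc:strict" = "false")
  mnt <- model$maintenance
  if (any(!is.na(unlist(mnt)))) {
    notes <- xml2::xml_add_child(mdl, "notes")
    body <- xml2::xml_add_child(notes, "body", xmlns = "http://www.w3.org/1999/xhtml")
    for (key in names(mnt)) {
      if (!is.na(mnt[[key]]))
        xml2::xml_add_child(body, "p", sprintf("%s: %.12g", toupper(key), mnt[[key]]))
    }
  }

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (i in seq_len(nrow(model$compartments))) {
    xml2::xml_add_child(lc, "compartment",
                        id = sid_encode(model$compartments$id[i]),
                        name = model$compartments$name[i],
                        constant = "true")
  }

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    met <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species",
                              id = paste0("M_", sid_encode(met$id)),
                              compartment = sid_encode(met$compartment),
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(met$name)) xml2::xml_set_attr(sp, "name", met$name)
    if (!is.na(met$charge)) xml2::xml_set_attr(sp, "fbc:charge", as.character(met$charge))
    if (!is.na(met$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", met$formula)
  }

  fmt1 <- function(v) vapply(v, function(x) format(x, digits = 17), character(1))
  bound_vals <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  bound_ids <- stats::setNames(sprintf("FB_%d", seq_along(bound_vals)), fmt1(bound_vals))
  bid <- function(v) unname(bound_ids[fmt1(v)])
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (k in seq_along(bound_vals)) {
    xml2::xml_add_child(lp, "parameter", id = sprintf("FB_%d", k),
                        value = format(bound_vals[k], digits = 17),
                        constant = "true")
  }

  add_gpa <- function(parent, node) {
    if (node$type == "leaf") {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = paste0("G_", sid_encode(node$gene)))
    } else {
      sub <- xml2::xml_add_child(parent, paste0("fbc:", node$type))
      for (ch in node$children) add_gpa(sub, ch)
    }
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rx <- xml2::xml_add_child(lr, "reaction",
                              id = paste0("R_", sid_encode(r$id)),
                              reversible = tolower(r$lower_bound < 0),
                              fast = "false",
                              "fbc:lowerFluxBound" = bid(r$lower_bound),
                              "fbc:upperFluxBound" = bid(r$upper_bound))
    if (!is.na(r$name)) xml2::xml_set_attr(rx, "name", r$name)
    if (r$is_exchange) xml2::xml_set_attr(rx, "sboTerm", "SBO:0000627")
    if (!is.na(r$subsystem)) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body", xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", r$subsystem))
    }
    st <- model$stoichiometry[model$stoichiometry$reaction == r$id, ]
    reac <- st[st$coefficient < 0, ]; prod <- st[st$coefficient > 0, ]
    if (nrow(reac)) {
      lrx <- xml2::xml_add_child(rx, "listOfReactants")
      for (j in seq_len(nrow(reac)))
        xml2::xml_add_child(lrx, "speciesReference",
                            species = paste0("M_", sid_encode(reac$metabolite[j])),
                            stoichiometry = format(-reac$coefficient[j], digits = 17),
                            constant = "true")
    }
    if (nrow(prod)) {
      lpx <- xml2::xml_add_child(rx, "listOfProducts")
      for (j in seq_len(nrow(prod)))
        xml2::xml_add_child(lpx, "speciesReference",
                            species = paste0("M_", sid_encode(prod$metabolite[j])),
                            stoichiometry = format(prod$coefficient[j], digits = 17),
                            constant = "true")
    }
    if (!is.na(r$gpr)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      add_gpa(gpa, parse_gpr(r$gpr))
    }
  }

  if (!is.na(model$objective)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", sid_encode(model$objective)),
                        "fbc:coefficient" = "1")
  }

  if (length(model$genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in model$genes)
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sid_encode(g)),
                          "fbc:label" = g)
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

strip_prefix <- function(ids, prefix) {
  if (length(ids) && all(startsWith(ids, prefix))) substring(ids, nchar(prefix) + 1)
  else ids
}

parse_notes_keyvals <- function(node, ns) {
  ps <- xml2::xml_find_all(node, ".//*[local-name()='p']")
  txt <- xml2::xml_text(ps)
  kv <- regmatches(txt, regexec("^\\s*([A-Za-z_/ ]+?)\\s*:\\s*(.*?)\\s*$", txt))
  out <- list()
  for (hit in kv) if (length(hit) == 3) out[[hit[2]]] <- hit[3]
  out
}

#' Read an SBML model (Level 3 + FBC v2, tolerant of older dialects)
#'
#' Understands FBC v2 (parameter-referenced bounds, gene-product
#' associations, active objective), FBC v1 flux bounds
#' (`fbc:listOfFluxBounds`), Level 2 COBRA-style kineticLaw
#' `LOWER_BOUND`/`UPPER_BOUND` parameters, and `GENE_ASSOCIATION` notes. A
#' reaction with no discoverable bounds, or a gene-product reference with no
#' declaration, is rejected with the offending id. Conventional
#' `M_`/`R_`/`G_` id prefixes are stripped when all ids of a category carry
#' them; escaped characters written by [write_sbml()] are decoded.
#'
#' @param path SBML file path.
#' @return A validated `gem`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  fbc_pre <- names(ns)[ns %in% c(FBC_V2_NS, FBC_V1_NS)][1]
  core_pre <- names(ns)[ns == SBML_CORE_NS][1]
  if (is.na(core_pre) || !length(core_pre)) core_pre <- names(ns)[1]
  q <- function(tag) paste0(core_pre, ":", tag)
  fq <- function(tag) paste0(fbc_pre, ":", tag)

  mdl <- xml2::xml_find_first(doc, paste0("./", q("model")), ns)
  model_id <- sid_decode(xml2::xml_attr(mdl, "id") %|NA|% "model")

  comp_nodes <- xml2::xml_find_all(mdl, paste0("./", q("listOfCompartments"), "/", q("compartment")), ns)
  compartments <- tibble::tibble(
    id = sid_decode(xml2::xml_attr(comp_nodes, "id")),
    name = xml2::xml_attr(comp_nodes, "name"))
  compartments$name[is.na(compartments$name)] <- compartments$id[is.na(compartments$name)]

  sp_nodes <- xml2::xml_find_all(mdl, paste0("./", q("listOfSpecies"), "/", q("species")), ns)
  raw_sp_ids <- xml2::xml_attr(sp_nodes, "id")
  sp_ids <- sid_decode(strip_prefix(raw_sp_ids, "M_"))
  metabolites <- tibble::tibble(
    id = sp_ids,
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = sid_decode(xml2::xml_attr(sp_nodes, "compartment")),
    formula = xml2::xml_attr(sp_nodes, "chemicalFormula"),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp_nodes, "charge"))))
  sp_map <- stats::setNames(sp_ids, raw_sp_ids)

  par_nodes <- xml2::xml_find_all(mdl, paste0("./", q("listOfParameters"), "/", q("parameter")), ns)
  par_vals <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                              xml2::xml_attr(par_nodes, "id"))

  # FBC v1 global flux bounds, if present
  fb_lower <- fb_upper <- character()
  if (!is.na(fbc_pre)) {
    fb_nodes <- xml2::xml_find_all(mdl, paste0(".//", fq("fluxBound")), ns)
    if (length(fb_nodes)) {
      fb_rxn <- xml2::xml_attr(fb_nodes, "reaction")
      fb_op <- xml2::xml_attr(fb_nodes, "operation")
      fb_val <- as.numeric(xml2::xml_attr(fb_nodes, "value"))
      fb_lower <- stats::setNames(fb_val[fb_op %in% c("greaterEqual", "equal")],
                                  fb_rxn[fb_op %in% c("greaterEqual", "equal")])
      fb_upper <- stats::setNames(fb_val[fb_op %in% c("lessEqual", "equal")],
                                  fb_rxn[fb_op %in% c("lessEqual", "equal")])
    }
  }

  gp_nodes <- if (!is.na(fbc_pre))
    xml2::xml_find_all(mdl, paste0(".//", fq("geneProduct")), ns) else list()
  gp_ids <- vapply(gp_nodes, function(x) xml2::xml_attr(x, "id"), character(1))
  gp_labels <- vapply(gp_nodes, function(x) xml2::xml_attr(x, "label"), character(1))
  gp_labels[is.na(gp_labels)] <- sid_decode(strip_prefix(gp_ids[is.na(gp_labels)], "G_"))
  gene_map <- stats::setNames(gp_labels, gp_ids)

  parse_gpa_node <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      if (!ref %in% names(gene_map))
        stop("unknown gene-product reference: ", ref)
      return(gpr_leaf(unname(gene_map[ref])))
    }
    kids <- xml2::xml_children(node)
    gpr_node(nm, lapply(kids, parse_gpa_node))
  }

  rxn_nodes <- xml2::xml_find_all(mdl, paste0("./", q("listOfReactions"), "/", q("reaction")), ns)
  raw_rxn_ids <- xml2::xml_attr(rxn_nodes, "id")
  rxn_ids <- sid_decode(strip_prefix(raw_rxn_ids, "R_"))
  rxn_rows <- list(); st_rows <- list()
  for (i in seq_along(rxn_nodes)) {
    node <- rxn_nodes[[i]]
    rid <- rxn_ids[i]
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    lb <- if (!is.na(lb_ref)) par_vals[[lb_ref]] else
      if (raw_rxn_ids[i] %in% names(fb_lower)) fb_lower[[raw_rxn_ids[i]]] else NA_real_
    ub <- if (!is.na(ub_ref)) par_vals[[ub_ref]] else
      if (raw_rxn_ids[i] %in% names(fb_upper)) fb_upper[[raw_rxn_ids[i]]] else NA_real_
    if (is.na(lb) || is.na(ub)) {
      # COBRA Level 2 dialect: kineticLaw local parameters
      kl <- xml2::xml_find_all(node, ".//*[local-name()='parameter' or local-name()='localParameter']")
      kl_ids <- vapply(kl, function(x) xml2::xml_attr(x, "id"), character(1))
      kl_val <- as.numeric(vapply(kl, function(x) xml2::xml_attr(x, "value"), character(1)))
      if (is.na(lb) && "LOWER_BOUND" %in% kl_ids) lb <- kl_val[match("LOWER_BOUND", kl_ids)]
      if (is.na(ub) && "UPPER_BOUND" %in% kl_ids) ub <- kl_val[match("UPPER_BOUND", kl_ids)]
    }
    if (is.na(lb) || is.na(ub))
      stop("no flux bounds found for reaction: ", rid)
    gpr <- NA_character_
    gpa <- xml2::xml_find_first(node, paste0("./", fq("geneProductAssociation")), ns)
    if (!is.na(fbc_pre) && !inherits(gpa, "xml_missing") && length(xml2::xml_children(gpa))) {
      gpr <- render_gpr(parse_gpa_node(xml2::xml_children(gpa)[[1]]))
    }
    subsystem <- NA_character_
    notes <- xml2::xml_find_first(node, paste0("./", q("notes")), ns)
    if (!inherits(notes, "xml_missing")) {
      kv <- parse_notes_keyvals(notes, ns)
      subsystem <- kv[["SUBSYSTEM"]] %||% NA_character_
      if (is.na(gpr) && !is.null(kv[["GENE_ASSOCIATION"]]) && nzchar(kv[["GENE_ASSOCIATION"]]))
        gpr <- render_gpr(parse_gpr(kv[["GENE_ASSOCIATION"]]))
    }
    sbo <- xml2::xml_attr(node, "sboTerm")
    is_ex <- identical(sbo, "SBO:0000627") ||
      (is.na(sbo) && startsWith(rid, "EX_"))
    rxn_rows[[i]] <- tibble::tibble(
      id = rid, name = xml2::xml_attr(node, "name"),
      lower_bound = lb, upper_bound = ub, gpr = gpr,
      subsystem = subsystem, is_exchange = is_ex)
    refs <- function(tag, sign) {
      sr <- xml2::xml_find_all(node, paste0("./", q(tag), "/", q("speciesReference")), ns)
      if (!length(sr)) return(NULL)
      tibble::tibble(reaction = rid,
                     metabolite = unname(sp_map[xml2::xml_attr(sr, "species")]),
                     coefficient = sign * as.numeric(xml2::xml_attr(sr, "stoichiometry")))
    }
    st_rows[[i]] <- dplyr::bind_rows(refs("listOfReactants", -1),
                                     refs("listOfProducts", 1))
  }
  stoich <- dplyr::bind_rows(st_rows)
  stoich <- dplyr::summarise(dplyr::group_by(stoich, .data$reaction, .data$metabolite),
                             coefficient = sum(.data$coefficient), .groups = "drop")
  stoich <- stoich[stoich$coefficient != 0, ]

  objective <- NA_character_
  if (!is.na(fbc_pre)) {
    lo <- xml2::xml_find_first(mdl, paste0("./", fq("listOfObjectives")), ns)
    if (!inherits(lo, "xml_missing")) {
      active <- xml2::xml_attr(lo, "activeObjective")
      objs <- xml2::xml_find_all(lo, paste0("./", fq("objective")), ns)
      obj_ids <- vapply(objs, function(x) xml2::xml_attr(x, "id"), character(1))
      pick <- if (!is.na(active) && active %in% obj_ids) which(obj_ids == active) else 1L
      if (length(objs)) {
        fo <- xml2::xml_find_first(objs[[pick]], paste0(".//", fq("fluxObjective")), ns)
        if (!inherits(fo, "xml_missing")) {
          oref <- xml2::xml_attr(fo, "reaction")
          objective <- rxn_ids[match(oref, raw_rxn_ids)]
          if (is.na(objective)) objective <- sid_decode(strip_prefix(oref, "R_"))
        }
      }
    }
  }

  maintenance <- list(gam = NA_real_, ngam = NA_real_, po_ratio = NA_real_)
  mnotes <- xml2::xml_find_first(mdl, paste0("./", q("notes")), ns)
  if (!inherits(mnotes, "xml_missing")) {
    kv <- parse_notes_keyvals(mnotes, ns)
    for (key in names(maintenance)) {
      v <- kv[[toupper(key)]]
      if (!is.null(v)) maintenance[[key]] <- as.numeric(v)
    }
  }

  reactions <- dplyr::bind_rows(rxn_rows)
  genes <- sort(unique(c(unname(gene_map),
                         unlist(lapply(reactions$gpr, function(g) gpr_genes(parse_gpr(g)))))))
  gem(model_id, compartments, metabolites, reactions, stoich,
      genes = genes, objective = objective, maintenance = maintenance)
}

`%|NA|%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
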