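#' Parse a reaction equation string
#'
#' Grammar: `"A_c + 2 B_c -> C_c"`; `->` marks an irreversible and `<=>`
#' (or `<->`) a reversible reaction (directionality information itself lives
#' in the bounds; the arrow is required syntax). Either side may be empty
#' (exchange/sink notation, e.g. `"A_e ->"`).
#'
#' @param equation equation string.
#' @return Named numeric vector metabolite -> signed coefficient
#'   (negative = consumed).
#' @export
parse_equation <- function(equation) {
  m <- regexpr("<=>|<->|=>|->", equation)
  if (m < 0) stop("malformed equation (no reaction arrow): ", equation)
  arrow <- regmatches(equation, m)
  sides <- strsplit(equation, "<=>|<->|=>|->")[[1]]
  lhs <- if (length(sides) >= 1) sides[1] else ""
  rhs <- if (length(sides) >= 2) sides[2] else ""
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric())
    terms <- trimws(strsplit(txt, "\\s\\+\\s|^\\+\\s|\\s\\+$")[[1]])
    terms <- terms[nzchar(terms)]
    out <- numeric()
    for (t in terms) {
      hit <- regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?\\s+)?(\\S+)$", t)[[1]]
      parts <- regmatches(t, regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?\\s+)?(\\S+)$", t))[[1]]
      if (length(parts) != 3 || !nzchar(parts[3]))
        stop("malformed equation term '", t, "' in: ", equation)
      coef <- if (nzchar(trimws(parts[2]))) as.numeric(parts[2]) else 1
      met <- parts[3]
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coef
    }
    out
  }
  l <- parse_side(lhs, -1); r <- parse_side(rhs, 1)
  coefs <- l
  for (met in names(r)) coefs[met] <- (if (met %in% names(coefs)) coefs[[met]] else 0) + r[[met]]
  coefs[coefs != 0]
}

render_equation <- function(stoich, reversible) {
  fmt <- function(v, met) {
    if (abs(v - 1) < 1e-12) met else paste(format(v, digits = 15), met)
  }
  lhs <- paste(mapply(fmt, -stoich[stoich < 0], names(stoich)[stoich < 0]),
               collapse = " + ")
  rhs <- paste(mapply(fmt, stoich[stoich > 0], names(stoich)[stoich > 0]),
               collapse = " + ")
  paste(lhs, if (reversible) "<=>" else "->", rhs)
}

#' Write a model as a directory of TSV tables
#'
#' Emits `model.tsv` (id, objective, maintenance), `compartments.tsv`,
#' `metabolites.tsv`, `reactions.tsv` (with the equation rendered in the
#' [parse_equation()] grammar) and `genes.tsv` — a diffable, bit-stable
#' mirror of the spreadsheet renderings that usually accompany published
#' reconstructions. Lossless against the in-memory model.
#'
#' @param model a `gem`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model_tables <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tibble::tibble(
    id = model$id, objective = model$objective,
    gam = model$maintenance$gam, ngam = model$maintenance$ngam,
    po_ratio = model$maintenance$po_ratio), file.path(dir, "model.tsv"))
  readr::write_tsv(model$compartments, file.path(dir, "compartments.tsv"))
  readr::write_tsv(model$metabolites, file.path(dir, "metabolites.tsv"))
  eqs <- vapply(model$reactions$id, function(rid) {
    st <- model$stoichiometry[model$stoichiometry$reaction == rid, ]
    render_equation(stats::setNames(st$coefficient, st$metabolite),
                    model$reactions$lower_bound[match(rid, model$reactions$id)] < 0)
  }, character(1))
  rxns <- model$reactions
  rxns$equation <- unname(eqs)
  readr::write_tsv(rxns[c("id", "name", "equation", "lower_bound", "upper_bound",
                          "gpr", "subsystem", "is_exchange")],
                   file.path(dir, "reactions.tsv"))
  readr::write_tsv(tibble::tibble(gene = model$genes), file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' Read a model from a directory of TSV tables
#'
#' Inverse of [write_model_tables()]; errors name any missing mandatory
#' column.
#'
#' @param dir directory containing the tables.
#' @return A validated `gem`.
#' @export
read_model_tables <- function(dir) {
  rd <- function(file, required, col_types = NULL) {
    path <- file.path(dir, file)
    if (!file.exists(path)) stop("missing table: ", path)
    df <- readr::read_tsv(path, show_col_types = FALSE, col_types = col_types)
    missing_c <- setdiff(required, names(df))
    if (length(missing_c))
      stop("table ", file, " is missing column(s): ", paste(missing_c, collapse = ", "))
    df
  }
  info <- rd("model.tsv", c("id", "objective"),
             readr::cols(id = "c", objective = "c", .default = "d"))
  comps <- rd("compartments.tsv", c("id", "name"), readr::cols(.default = "c"))
  mets <- rd("metabolites.tsv", c("id", "compartment"),
             readr::cols(charge = "i", .default = "c"))
  rxns <- rd("reactions.tsv", c("id", "equation", "lower_bound", "upper_bound"),
             readr::cols(lower_bound = "d", upper_bound = "d",
                         is_exchange = "l", .default = "c"))
  genes <- rd("genes.tsv", "gene")$gene
  st <- dplyr::bind_rows(lapply(seq_len(nrow(rxns)), function(i) {
    coefs <- parse_equation(rxns$equation[i])
    tibble::tibble(reaction = rxns$id[i], metabolite = names(coefs),
                   coefficient = unname(coefs))
  }))
  gem(info$id[1], comps, mets, rxns, st, genes = genes,
      objective = info$objective[1],
      maintenance = list(gam = info$gam[1] %|NA|% NA_real_,
                         ngam = info$ngam[1] %|NA|% NA_real_,
                         po_ratio = info$po_ratio[1] %|NA|% NA_real_))
}
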