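#' Construct an expression set
#'
#' A long-format table of per-replicate, per-condition expression evidence
#' (gene, condition, replicate, value). Values are non-negative abundances;
#' only zero vs non-zero is ever interpreted downstream. Genes absent from a
#' condition are "no evidence", not zero.
#'
#' @param data data frame with columns `gene`, `condition`, `replicate`,
#'   `value`.
#' @return A tibble of class `expression_set`.
#' @export
expression_set <- function(data) {
  data <- tibble::as_tibble(data)
  req <- c("gene", "condition", "replicate", "value")
  missing_c <- setdiff(req, names(data))
  if (length(missing_c)) stop("missing column(s): ", paste(missing_c, collapse = ", "))
  data <- data[req]
  if (any(is.na(data$value)) || any(data$value < 0))
    stop("expression values must be non-negative and non-missing")
  dup <- duplicated(data[c("gene", "condition", "replicate")])
  if (any(dup)) {
    d <- data[dup, ][1, ]
    stop(sprintf("duplicate entry for gene %s, condition %s, replicate %s",
                 d$gene, d$condition, d$replicate))
  }
  class(data) <- c("expression_set", class(tibble::tibble()))
  data
}

#' Read an expression table from a TSV file
#'
#' Expects long format with columns `gene`, `condition`, `replicate`,
#' `value`; see [expression_set()] for the validation rules.
#'
#' @param path file path.
#' @return An `expression_set`.
#' @export
read_expression <- function(path) {
  # condition ids like "30D" must never be parsed as Fortran-style doubles
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                        col_types = readr::cols(gene = "c", condition = "c",
                                                replicate = "c", value = "d"))
  expression_set(df)
}

#' Write an expression set to TSV
#' @param expr an `expression_set`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(tibble::as_tibble(expr), path)
  invisible(path)
}

#' Conditions present in an expression set
#' @param expr an `expression_set`.
#' @return Character vector.
#' @export
expression_conditions <- function(expr) unique(expr$condition)

#' Call inactive genes for one condition
#'
#' A gene is called inactive when it has a recorded value in every replicate
#' of the condition and all those values are exactly zero. No abundance
#' threshold is applied: any positive value in any replicate keeps the gene
#' active, and a gene missing from the table is active (no evidence).
#'
#' @param expr an `expression_set`.
#' @param condition condition id.
#' @return Sorted character vector of inactive gene ids.
#' @export
call_inactive_genes <- function(expr, condition) {
  cond <- condition
  if (!cond %in% expr$condition) stop("unknown condition: ", cond)
  sub <- expr[expr$condition == cond, ]
  n_rep <- length(unique(sub$replicate))
  byg <- dplyr::summarise(dplyr::group_by(sub, .data$gene),
                          n = dplyr::n(),
                          all_zero = all(.data$value == 0),
                          .groups = "drop")
  sort(byg$gene[byg$n == n_rep & byg$all_zero])
}

#' Genes inactive in at least one condition
#'
#' Union of the per-condition inactive calls over the given conditions —
#' used when the inactivity evidence is pooled across a whole experiment
#' (including conditions excluded from downstream modelling).
#'
#' @param expr an `expression_set`.
#' @param conditions conditions to pool (default: all).
#' @return Sorted character vector of gene ids.
#' @export
inactive_in_any_condition <- function(expr, conditions = expression_conditions(expr)) {
  sort(unique(unlist(lapply(conditions, call_inactive_genes, expr = expr))))
}
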