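#' Construct a medium definition
#'
#' A medium is a set of exchange-reaction bound overrides: the compounds the
#' cell may take up (negative lower bound) or must secrete. Applying a medium
#' closes the uptake of every exchange it does not list.
#'
#' @param name medium name.
#' @param bounds data frame with columns `reaction`, `lower`, `upper`, or a
#'   named list `reaction = c(lower, upper)`.
#' @param description free-text description.
#' @return An object of class `medium`.
#' @export
medium <- function(name, bounds, description = "") {
  if (!is.data.frame(bounds) && length(bounds) == 0) {
    bounds <- tibble::tibble(reaction = character(), lower = numeric(),
                             upper = numeric())
  } else if (!is.data.frame(bounds)) {
    bounds <- tibble::tibble(
      reaction = names(bounds),
      lower = vapply(bounds, function(x) as.numeric(x[[1]]), numeric(1)),
      upper = vapply(bounds, function(x) as.numeric(x[[2]]), numeric(1)))
  }
  bounds <- tibble::as_tibble(bounds)[c("reaction", "lower", "upper")]
  bad <- bounds$reaction[bounds$lower > bounds$upper]
  if (length(bad)) stop("medium lower bound exceeds upper bound for: ",
                        paste(bad, collapse = ", "))
  structure(list(name = name, bounds = bounds, description = description),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> %s: %d exchange bound(s)\n", x$name, nrow(x$bounds)))
  invisible(x)
}

#' Read a medium definition from YAML
#'
#' Expected layout:
#' ```yaml
#' name: minimal_glucose
#' description: Defined minimal medium, glucose as carbon source
#' bounds:
#'   EX_glc: [-10, 0]
#'   EX_o2: [-1000, 0]
#' ```
#'
#' @param path YAML file path.
#' @return A `medium`.
#' @export
read_medium <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$bounds)) stop("medium file has no 'bounds' section: ", path)
  medium(y$name %||% basename(path), y$bounds, y$description %||% "")
}

#' Write a medium definition to YAML
#' @param med a `medium`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_medium <- function(med, path) {
  bounds <- stats::setNames(
    lapply(seq_len(nrow(med$bounds)),
           function(i) c(med$bounds$lower[i], med$bounds$upper[i])),
    med$bounds$reaction)
  yaml::write_yaml(list(name = med$name, description = med$description,
                        bounds = bounds), path)
  invisible(path)
}

#' Apply a medium to a model
#'
#' Exchange reactions listed in the medium get exactly the stated bounds;
#' every other exchange reaction has its uptake closed (lower bound raised to
#' 0 — never widened). Non-exchange reactions are untouched. The operation is
#' idempotent.
#'
#' @param model a `gem`.
#' @param med a `medium`.
#' @return A new `gem`.
#' @export
apply_medium <- function(model, med) {
  stopifnot(inherits(med, "medium"))
  ex <- exchange_reactions(model)
  unknown <- setdiff(med$bounds$reaction, model$reactions$id)
  if (length(unknown)) stop("medium references unknown reaction(s): ",
                            paste(unknown, collapse = ", "))
  non_ex <- setdiff(med$bounds$reaction, ex)
  if (length(non_ex)) stop("medium references non-exchange reaction(s): ",
                           paste(non_ex, collapse = ", "))
  closed <- setdiff(ex, med$bounds$reaction)
  idx <- match(closed, model$reactions$id)
  model$reactions$lower_bound[idx] <- pmax(model$reactions$lower_bound[idx], 0)
  idx <- match(med$bounds$reaction, model$reactions$id)
  model$reactions$lower_bound[idx] <- med$bounds$lower
  model$reactions$upper_bound[idx] <- med$bounds$upper
  model
}
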