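aa_three_letter <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
                     Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
                     L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
                     S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

monomer_alphabets <- list(
  dna = c(A = "dA", C = "dC", G = "dG", T = "dT"),
  rna = c(A = "A", C = "C", G = "G", U = "U"),
  protein = aa_three_letter)

#' Monomer mole fractions from weighted sequences
#'
#' Computes the mole fraction of each monomer (deoxynucleotide, nucleotide
#' or amino-acid residue) from a set of sequences with abundance weights —
#' the way nucleotide composition is derived from a genome, ribonucleotide
#' composition from a transcriptome (with rRNA/tRNA weights), and amino-acid
#' composition from a proteome:
#' \deqn{f_m = \sum_s w_s n_m(s) \;/\; \sum_s w_s \,\ell(s).}
#'
#' @param sequences list of `(sequence, weight)` pairs, or a data frame with
#'   columns `sequence` and `weight`.
#' @param alphabet `"dna"`, `"rna"` or `"protein"`.
#' @return Named numeric vector of mole fractions summing to 1; names are
#'   `dA/dC/dG/dT`, `A/C/G/U` or three-letter amino-acid codes.
#' @examples
#' monomer_fractions_from_sequences(
#'   list(list("AAT", 2), list("G", 1)), alphabet = "dna")
#' @export
monomer_fractions_from_sequences <- function(sequences,
                                             alphabet = c("dna", "rna", "protein")) {
  alphabet <- match.arg(alphabet)
  map <- monomer_alphabets[[alphabet]]
  if (is.data.frame(sequences)) {
    sequences <- purrr::map2(sequences$sequence, sequences$weight, list)
  }
  counts <- stats::setNames(numeric(length(map)), unname(map))
  total <- 0
  for (k in seq_along(sequences)) {
    s <- toupper(sequences[[k]][[1]])
    w <- as.numeric(sequences[[k]][[2]])
    if (w < 0) stop("sequence weights must be non-negative")
    if (w == 0 || !nchar(s)) next
    chars <- strsplit(s, "")[[1]]
    bad <- which(!chars %in% names(map))
    if (length(bad))
      stop(sprintf("invalid character '%s' at position %d of sequence %d (%s alphabet)",
                   chars[bad[1]], bad[1], k, alphabet))
    tb <- table(chars)
    counts[map[names(tb)]] <- counts[map[names(tb)]] + w * as.numeric(tb)
    total <- total + w * length(chars)
  }
  if (total == 0) stop("all sequence weights are zero or sequences empty")
  counts / total
}

#' Construct a biomass composition
#'
#' Holds everything needed to build a biomass equation: macromolecular mass
#' fractions (g per g dry weight), per-class monomer mole fractions, residue
#' masses (g/mmol of *polymer-incorporated* residue, i.e. the free monomer
#' minus water for the polymerising classes — the convention that makes the
#' assembled equation close to exactly 1 g/gDW), the cell wall carbohydrate
#' split, the trehalose:amylose molar ratio for the remaining carbohydrate
#' mass, and the growth-associated maintenance (GAM, mmol ATP/gDW).
#'
#' @param macro_fractions named numeric, g/gDW per class (must sum to
#'   1 within 0.01).
#' @param monomer_fractions named list class -> named mole-fraction vector
#'   (each summing to 1 within 1e-9).
#' @param monomer_masses named numeric, residue mass g/mmol per monomer id.
#' @param cell_wall_split named numeric `glucan`, `mannan`, `chitin`
#'   (g/gDW), optional.
#' @param trehalose_amylose_molar_ratio numeric, optional.
#' @param gam growth-associated maintenance, mmol ATP/gDW.
#' @return An object of class `biomass_composition`.
#' @export
biomass_composition <- function(macro_fractions, monomer_fractions,
                                monomer_masses, cell_wall_split = NULL,
                                trehalose_amylose_molar_ratio = NA_real_,
                                gam = 0) {
  tot <- sum(macro_fractions)
  if (abs(tot - 1) > 0.01)
    stop(sprintf("macromolecular fractions sum to %.4f g/gDW, expected 1 +/- 0.01", tot))
  for (cls in names(monomer_fractions)) {
    if (!cls %in% names(macro_fractions))
      stop("monomer fractions given for unknown class: ", cls)
    s <- sum(monomer_fractions[[cls]])
    if (abs(s - 1) > 1e-9)
      stop(sprintf("monomer fractions for class %s sum to %.12f, expected 1", cls, s))
    missing_m <- setdiff(names(monomer_fractions[[cls]]), names(monomer_masses))
    if (length(missing_m)) stop("no residue mass for monomer(s): ",
                                paste(missing_m, collapse = ", "))
  }
  if (any(monomer_masses <= 0)) stop("residue masses must be positive")
  structure(list(macro_fractions = macro_fractions,
                 monomer_fractions = monomer_fractions,
                 monomer_masses = monomer_masses,
                 cell_wall_split = cell_wall_split,
                 trehalose_amylose_molar_ratio = trehalose_amylose_molar_ratio,
                 gam = gam),
            class = "biomass_composition")
}

#' Read a biomass composition from YAML
#'
#' Layout mirrors the composition tables shipped with yeast reconstructions:
#' `macro_fractions`, `monomer_fractions` (per class), `monomer_masses`,
#' optional `cell_wall_split`, `trehalose_amylose_molar_ratio`, `gam`.
#'
#' @param path YAML file path.
#' @return A `biomass_composition`.
#' @export
read_biomass_composition <- function(path) {
  y <- yaml::read_yaml(path)
  biomass_composition(
    macro_fractions = unlist(y$macro_fractions),
    monomer_fractions = lapply(y$monomer_fractions, unlist),
    monomer_masses = unlist(y$monomer_masses),
    cell_wall_split = if (!is.null(y$cell_wall_split)) unlist(y$cell_wall_split),
    trehalose_amylose_molar_ratio = y$trehalose_amylose_molar_ratio %||% NA_real_,
    gam = y$gam %||% 0)
}

#' Scale a composition to stoichiometric biomass coefficients
#'
#' Converts mass fractions to the mmol/gDW coefficients of the per-class
#' biomass pseudo-reactions: for class \eqn{c} with mass fraction \eqn{F_c}
#' and monomer mole fractions \eqn{f_m} with residue masses \eqn{M_m}
#' (g/mmol),
#' \deqn{\mathrm{coeff}_{c,m} = F_c\, f_m \,/\, \textstyle\sum_k f_k M_k,}
#' so that the total assembled mass \eqn{\sum \mathrm{coeff} \cdot M} is
#' exactly 1 g per g dry weight.
#'
#' @param comp a `biomass_composition`.
#' @return Long tibble with columns `class`, `monomer`, `coefficient`
#'   (mmol/gDW); classes with zero mass fraction contribute no rows.
#' @export
scale_to_biomass <- function(comp) {
  stopifnot(inherits(comp, "biomass_composition"))
  rows <- list()
  for (cls in names(comp$monomer_fractions)) {
    Fc <- comp$macro_fractions[[cls]]
    if (Fc == 0) next
    f <- comp$monomer_fractions[[cls]]
    m <- comp$monomer_masses[names(f)]
    denom <- sum(f * m)
    if (denom <= 0) stop("zero total monomer mass for class ", cls)
    rows[[cls]] <- tibble::tibble(class = cls, monomer = names(f),
                                  coefficient = Fc * unname(f) / denom)
  }
  dplyr::bind_rows(rows)
}

#' Total mass of a scaled biomass equation
#'
#' @param coefficients output of [scale_to_biomass()].
#' @param monomer_masses named residue masses (g/mmol).
#' @return Total mass in g/gDW (1 for a valid composition).
#' @export
biomass_mass <- function(coefficients, monomer_masses) {
  sum(coefficients$coefficient * monomer_masses[coefficients$monomer])
}

#' Partition total carbohydrate mass into wall and storage carbohydrates
#'
#' The structural wall carbohydrates (glucan, mannan, chitin) are measured;
#' the remaining carbohydrate mass is split between the storage
#' carbohydrates trehalose and amylose so that their molar ratio equals the
#' given value.
#'
#' @param total_carb total carbohydrate mass, g/gDW.
#' @param wall named numeric `glucan`, `mannan`, `chitin` (g/gDW).
#' @param ratio trehalose:amylose molar ratio.
#' @param masses named numeric with `trehalose` and `amylose` molar masses
#'   (g/mmol).
#' @return Named numeric vector of g/gDW over
#'   `glucan, mannan, chitin, trehalose, amylose`.
#' @export
partition_carbohydrates <- function(total_carb, wall, ratio, masses) {
  wall_sum <- sum(wall)
  if (wall_sum > total_carb + 1e-12)
    stop(sprintf("wall carbohydrate mass (%.4f) exceeds total carbohydrate (%.4f)",
                 wall_sum, total_carb))
  remainder <- max(total_carb - wall_sum, 0)
  Mt <- masses[["trehalose"]]; Ma <- masses[["amylose"]]
  if (remainder == 0) {
    tre <- 0; amy <- 0
  } else {
    # moles_t / moles_a = ratio; masses t = n_t Mt, a = n_a Ma; t + a = remainder
    n_a <- remainder / (ratio * Mt + Ma)
    amy <- n_a * Ma
    tre <- remainder - amy
  }
  c(wall[c("glucan", "mannan", "chitin")], trehalose = tre, amylose = amy)
}

#' Assemble biomass pseudo-reactions into a model
#'
#' Adds (or replaces, so re-assembly is idempotent) one pseudo-reaction per
#' macromolecule class — consuming its monomers at the scaled coefficients
#' and producing a class pseudo-metabolite — plus a top-level biomass
#' reaction consuming one unit of every class pseudo-metabolite together
#' with the growth-associated maintenance ATP hydrolysis
#' (GAM ATP + GAM H2O -> GAM ADP + GAM Pi + GAM H; omitted entirely when
#' `gam = 0`). The biomass reaction becomes the model objective.
#'
#' @param model a `gem` containing every monomer metabolite.
#' @param coefficients long tibble from [scale_to_biomass()] (columns
#'   `class`, `monomer`, `coefficient`); monomer ids must be model
#'   metabolite ids.
#' @param gam growth-associated maintenance (mmol ATP/gDW).
#' @param atp named character vector with metabolite ids `atp`, `h2o`,
#'   `adp`, `pi`, `h`; required when `gam > 0`.
#' @param compartment compartment for the class pseudo-metabolites
#'   (default: cytosol role, else first compartment).
#' @return The model with pseudo-reactions added and objective set to
#'   `"BIOMASS"`.
#' @export
assemble_biomass <- function(model, coefficients, gam = 0, atp = NULL,
                             compartment = NULL) {
  missing_m <- setdiff(unique(coefficients$monomer), model$metabolites$id)
  if (length(missing_m))
    stop("monomer metabolite(s) missing from model: ",
         paste(missing_m, collapse = ", "))
  if (gam > 0) {
    need <- c("atp", "h2o", "adp", "pi", "h")
    if (is.null(atp) || !all(need %in% names(atp)))
      stop("gam > 0 requires atp metabolite ids: ", paste(need, collapse = ", "))
    missing_m <- setdiff(unname(atp[need]), model$metabolites$id)
    if (length(missing_m))
      stop("maintenance metabolite(s) missing from model: ",
           paste(missing_m, collapse = ", "))
  }
  comp_id <- compartment %||% compartment_roles(model)[["cytosol"]] %||%
    model$compartments$id[1]
  classes <- unique(coefficients$class)
  drop_ids <- c(paste0("PSEUDO_", classes), "BIOMASS")
  model <- remove_reactions(model, drop_ids)
  bio_stoich <- numeric()
  for (cls in classes) {
    sub <- coefficients[coefficients$class == cls, ]
    pseudo_met <- paste0("biomass_", cls, "_", comp_id)
    model <- add_metabolite(model, pseudo_met, comp_id,
                            name = paste(cls, "pseudo-metabolite"))
    model <- add_reaction(model, paste0("PSEUDO_", cls),
                          c(stats::setNames(-sub$coefficient, sub$monomer),
                            stats::setNames(1, pseudo_met)),
                          lower = 0, upper = 1000,
                          name = paste(cls, "pseudo-reaction"),
                          subsystem = "biomass")
    bio_stoich[pseudo_met] <- -1
  }
  if (gam > 0) {
    bio_stoich[atp[["atp"]]] <- (bio_stoich[atp[["atp"]]] %|na|% 0) - gam
    bio_stoich[atp[["h2o"]]] <- (bio_stoich[atp[["h2o"]]] %|na|% 0) - gam
    bio_stoich[atp[["adp"]]] <- (bio_stoich[atp[["adp"]]] %|na|% 0) + gam
    bio_stoich[atp[["pi"]]] <- (bio_stoich[atp[["pi"]]] %|na|% 0) + gam
    bio_stoich[atp[["h"]]] <- (bio_stoich[atp[["h"]]] %|na|% 0) + gam
  }
  model <- add_reaction(model, "BIOMASS", bio_stoich, lower = 0, upper = 1000,
                        name = "biomass", subsystem = "biomass")
  model$objective <- "BIOMASS"
  model$maintenance$gam <- gam
  validate_gem(model)
  model
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Set the non-growth-associated maintenance
#'
#' NGAM is a fixed ATP hydrolysis drain the cell pays regardless of growth,
#' implemented as a lower bound on an ATP hydrolysis reaction (added as
#' `NGAM` if absent).
#'
#' @param model a `gem`.
#' @param ngam maintenance flux (mmol ATP/gDW/h).
#' @param atp named character vector with ids `atp`, `h2o`, `adp`, `pi`,
#'   `h`; needed only when the `NGAM` reaction does not yet exist.
#' @return The modified model.
#' @export
set_ngam <- function(model, ngam, atp = NULL) {
  if (!"NGAM" %in% model$reactions$id) {
    need <- c("atp", "h2o", "adp", "pi", "h")
    if (is.null(atp) || !all(need %in% names(atp)))
      stop("adding an NGAM reaction requires atp metabolite ids: ",
           paste(need, collapse = ", "))
    model <- add_reaction(model, "NGAM",
                          stats::setNames(c(-1, -1, 1, 1, 1),
                                          unname(atp[need])),
                          lower = ngam, upper = 1000,
                          name = "non-growth-associated maintenance")
  } else {
    model <- set_bounds(model, "NGAM", lower = ngam)
  }
  model$maintenance$ngam <- ngam
  model
}
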