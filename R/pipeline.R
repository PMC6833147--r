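#' Run the full condition-comparison study workflow
#'
#' Orchestrates the whole analysis: load the model, media and expression
#' data; call inactive genes per condition; derive condition-specific
#' models; detect and rescue auxotrophies among the biomass components;
#' compute the condition report and the surplus-capacity table at the
#' configured growth fraction; and write everything (condition models as
#' SBML, reports as TSV, a log, and a config snapshot) to the output
#' directory. Outputs are deterministic for fixed inputs and seed, and every
#' TSV carries the config hash in a leading comment line.
#'
#' @param config path to a YAML configuration, or an equivalent named list,
#'   with fields: `model` (SBML path), `medium` (YAML path), `expression`
#'   (TSV path), `conditions` (character), `components` (character),
#'   `growth_fraction` (default 0.9), `union_conditions` (conditions pooled
#'   for the inactive-in-any-condition gene list; default all in the
#'   expression data), `seed` (default 1), `out_dir`.
#' @return Invisibly, a list with `report`, `surplus`, `condition_models`,
#'   `inactive_any`, `config_hash`, `out_dir`.
#' @export
run_study <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  } else {
    config_dir <- "."
  }
  need <- c("model", "medium", "expression", "conditions", "components", "out_dir")
  missing_f <- setdiff(need, names(config))
  if (length(missing_f)) stop("config is missing field(s): ",
                              paste(missing_f, collapse = ", "))
  resolve <- function(p) if (file.exists(p)) p else file.path(config_dir, p)
  fraction <- config$growth_fraction %||% 0.9
  if (fraction < 0 || fraction > 1) stop("growth_fraction must be in [0, 1]")
  seed <- as.integer(config$seed %||% 1L)
  cfg_hash <- rlang::hash(config[order(names(config))])
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf(name, paste("FAILED:", conditionMessage(e)))
      stop(sprintf("stage '%s' failed: %s (check inputs listed in the config)",
                   name, conditionMessage(e)), call. = FALSE)
    })
  }
  write_report <- function(df, file) {
    path <- file.path(out_dir, file)
    con <- file(path, "w")
    cat(sprintf("# gemkit config %s\n", cfg_hash), file = con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }

  set.seed(seed)
  model <- stage("load_model", read_sbml(resolve(config$model)))
  logf("load_model", sprintf("%s: %d reactions, %d metabolites, %d genes",
                             model$id, nrow(model$reactions),
                             nrow(model$metabolites), length(model$genes)))
  med <- stage("load_medium", read_medium(resolve(config$medium)))
  expr <- stage("load_expression", read_expression(resolve(config$expression)))

  base <- apply_medium(model, med)
  base_sol <- stage("validate", solve_fba(base))
  logf("validate", sprintf("base model growth: %s (%.6g)", base_sol$status,
                           base_sol$objective))

  inactive_any <- inactive_in_any_condition(expr)
  logf("inactive_union", sprintf("%d gene(s) inactive in at least one condition",
                                 length(inactive_any)))

  components <- as.character(config$components)
  cms <- list()
  for (cond in config$conditions) {
    cm <- stage(paste0("condition_", cond), {
      inact <- call_inactive_genes(expr, cond)
      cm <- derive_condition_model(apply_medium(model, med), inact, condition = cond)
      aux <- detect_auxotrophies(cm, components)
      if (length(aux)) cm <- rescue_auxotrophies(cm, aux)
      cm
    })
    logf(paste0("condition_", cond),
         sprintf("%d inactive, %d deactivated, %d auxotrophies rescued",
                 length(cm$inactive_genes), length(cm$deactivated_reactions),
                 length(cm$rescued_metabolites)))
    cms[[cond]] <- cm
    write_sbml(cm$model, file.path(out_dir, paste0("cm_", cond, ".xml")))
  }

  report <- stage("report", condition_report(cms, growth_fraction = fraction))
  surplus <- stage("surplus", surplus_table(cms, components, fraction = fraction))
  write_report(report, "condition_report.tsv")
  write_report(tibble::as_tibble(surplus), "surplus_table.tsv")
  write_report(tibble::tibble(gene = inactive_any), "inactive_in_any_condition.tsv")
  yaml::write_yaml(c(config, list(config_hash = cfg_hash)),
                   file.path(out_dir, "config_snapshot.yaml"))
  logf("done", sprintf("outputs in %s (config %s)", out_dir, cfg_hash))
  invisible(list(report = report, surplus = surplus, condition_models = cms,
                 inactive_any = inactive_any, config_hash = cfg_hash,
                 out_dir = out_dir))
}
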