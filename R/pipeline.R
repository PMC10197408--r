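#' Pipeline configuration
#'
#' Validates and assembles the configuration for [run_pipeline()]: either
#' paths to existing microdata/macro CSVs or a [generator_config()] for
#' synthetic input, the disability domains to analyse, imputation settings
#' and the decomposition model.  Can also be loaded from YAML with
#' `pipeline_config_from_yaml()`.
#'
#' @param out_dir output directory (created if absent).
#' @param domains nonempty subset of `c("adl", "iadl", "mobility")`.
#' @param generator a [generator_config()], used when no `microdata_path`.
#' @param microdata_path,macro_path optional CSV inputs replacing the
#'   generator.
#' @param missingness inject missingness per the generator config before
#'   imputation (synthetic input only).
#' @param impute logical: run chained-equation imputation.
#' @param m,cycles,donors imputation settings (see [imputation_schema()]).
#' @param model decomposition model (see [fit_two_level()]).
#' @param weighted use sampling weights throughout.
#' @param seed master seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            domains = c("adl", "iadl", "mobility"),
                            generator = generator_config(),
                            microdata_path = NULL, macro_path = NULL,
                            missingness = FALSE, impute = missingness,
                            m = 5L, cycles = 5L, donors = 5L,
                            model = c("random-intercept", "cluster-robust"),
                            weighted = TRUE, seed = 1L) {
  if (!length(domains))
    stop("pipeline_config: 'domains' must be nonempty")
  bad <- setdiff(domains, c("adl", "iadl", "mobility"))
  if (length(bad))
    stop("pipeline_config: unknown domain(s): ", paste(bad, collapse = ", "))
  if (!is.null(microdata_path) && !file.exists(microdata_path))
    stop("pipeline_config: microdata_path does not exist: ", microdata_path)
  if (!is.null(macro_path) && !file.exists(macro_path))
    stop("pipeline_config: macro_path does not exist: ", macro_path)
  cfg <- list(out_dir = out_dir, domains = domains, generator = generator,
              microdata_path = microdata_path, macro_path = macro_path,
              missingness = missingness, impute = impute,
              m = as.integer(m), cycles = as.integer(cycles),
              donors = as.integer(donors), model = match.arg(model),
              weighted = weighted, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file with fields matching the `pipeline_config()`
#'   arguments (generator settings under a `generator:` block).
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- do.call(generator_config, as.list(y$generator %||% list()))
  args <- y[setdiff(names(y), "generator")]
  do.call(pipeline_config, c(args, list(generator = gen)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full inequality-analysis pipeline
#'
#' Executes simulate (or load) -> optional missingness + imputation ->
#' age-post-stratified prevalence (by country and by income quintile, with
#' quintile percentage differences) -> within-country and overall Erreygers
#' concentration indices -> pooled two-level RIF decomposition, writing all
#' stage tables under `config$out_dir` together with a JSON run manifest
#' (package version, seed, stage file checksums).  Rerunning with the same
#' config reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with elements `prevalence`,
#'   `quintile_prevalence`, `pct_difference`, `indices`, `overall`,
#'   `decomposition`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(tab, name, ...) {
    p <- file.path(config$out_dir, name)
    write_table(tab, p, ...)
    written <<- c(written, p)
    p
  }

  # --- stage 1: data -------------------------------------------------------
  if (is.null(config$microdata_path)) {
    gen <- config$generator
    gen$seed <- config$seed
    micro <- generate_microdata(gen)
    macro <- generate_macro(gen)
    if (config$missingness && gen$missing_rate > 0) {
      micro <- inject_missingness(micro, rate = gen$missing_rate,
                                  mechanism = gen$missing_mechanism,
                                  vars = gen$missing_vars,
                                  seed = config$seed + 2L)
    }
    write_microdata(micro, file.path(config$out_dir, "microdata.csv"))
    utils::write.csv(macro, file.path(config$out_dir, "macro.csv"),
                     row.names = FALSE)
    written <- c(written, file.path(config$out_dir, "microdata.csv"),
                 file.path(config$out_dir, "macro.csv"))
  } else {
    micro <- read_microdata(config$microdata_path)
    macro <- utils::read.csv(config$macro_path, stringsAsFactors = FALSE)
  }
  ref <- reference_age_structure()

  # --- stage 2: imputation -------------------------------------------------
  has_missing <- any(vapply(c("marital", "education", "chronic", "smoke",
                              "drink"),
                            function(v) anyNA(micro[[v]]), logical(1)))
  if (config$impute && has_missing) {
    sch <- imputation_schema(m = config$m, cycles = config$cycles,
                             donors = config$donors,
                             seed = config$seed + 3L)
    imputed <- impute_chained(micro, sch)
  } else {
    imputed <- list(micro)
  }

  # --- stage 3: prevalence -------------------------------------------------
  prev <- prevalence_table(micro, ref, domains = config$domains)
  prev_q <- prevalence_table(micro, ref, domains = config$domains,
                             by_quintile = TRUE)
  pd <- do.call(rbind, lapply(split(prev_q,
                                    prev_q[c("domain", "country_code")],
                                    drop = TRUE), function(g) {
    data.frame(domain = g$domain[1L], country_code = g$country_code[1L],
               pct_difference = percentage_difference(
                 g$prevalence[g$quintile == 1L],
                 g$prevalence[g$quintile == 5L]),
               stringsAsFactors = FALSE)
  }))
  rownames(pd) <- NULL
  emit(prev, "prevalence.tsv")
  emit(prev_q, "quintile_prevalence.tsv")
  emit(pd, "percentage_difference.tsv")

  # --- stage 4: inequality -------------------------------------------------
  idx <- do.call(rbind, lapply(config$domains, function(dom)
    country_indices(micro, dom, weighted = config$weighted)))
  overall <- lapply(config$domains, function(dom)
    overall_index(micro, dom, weighted = config$weighted))
  names(overall) <- config$domains
  ov <- data.frame(domain = config$domains,
                   n = vapply(overall, `[[`, 0, "n"),
                   index = vapply(overall, `[[`, 0, "value"),
                   se = vapply(overall, `[[`, 0, "se"),
                   ci_low = vapply(overall, function(o) o$ci95[1L], 0),
                   ci_high = vapply(overall, function(o) o$ci95[2L], 0),
                   stringsAsFactors = FALSE)
  emit(idx, "inequality.tsv")
  emit(ov, "inequality_overall.tsv")

  # --- stage 5: decomposition ----------------------------------------------
  decomp <- list()
  for (dom in config$domains) {
    res <- decompose_inequality(imputed, macro, dom,
                                weighted = config$weighted,
                                model = config$model)
    decomp[[dom]] <- res
    tab <- res$coefficients
    tab$significant_0.05 <- tab$p_value < 0.05
    emit(tab, sprintf("decomposition_%s.tsv", dom))
  }

  manifest <- list(
    package = "rifineq",
    version = as.character(utils::packageVersion("rifineq")),
    seed = config$seed, domains = config$domains,
    model = config$model, m_imputations = length(imputed),
    files = as.list(stats::setNames(unname(tools::md5sum(written)),
                                    basename(written))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(prevalence = prev, quintile_prevalence = prev_q,
                 pct_difference = pd, indices = idx, overall = overall,
                 decomposition = decomp, manifest = manifest))
}
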