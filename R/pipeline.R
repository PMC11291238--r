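#' Serialize a model configuration to YAML
#'
#' @param config A [ce_config()] object.
#' @param path Destination YAML path.
#' @return `config`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ce_config"))
  ser_fit <- function(f) {
    if (is.null(f)) return(NULL)
    list(family = f$family, params = as.list(f$params))
  }
  ser_arm <- function(a) {
    list(
      name = a$name,
      drug_cost_per_cycle = a$drug_cost_per_cycle,
      os_fit = ser_fit(a$os_fit),
      pfs_fit = ser_fit(a$pfs_fit),
      ae_profile = lapply(seq_len(nrow(a$ae_profile)), function(i) {
        as.list(a$ae_profile[i, ])
      })
    )
  }
  obj <- list(
    inputs = unclass(config$inputs),
    intervention = ser_arm(config$intervention),
    comparator = ser_arm(config$comparator),
    params = if (!is.null(config$params)) {
      lapply(seq_len(nrow(config$params)), function(i) {
        as.list(config$params[i, ])
      })
    },
    curves = config$curves
  )
  yaml::write_yaml(obj, path)
  invisible(config)
}

#' Read a model configuration from YAML
#'
#' @param path YAML path written by [write_config()] (or hand-authored in
#'   the same layout).
#' @return A [ce_config()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config not found: ", path))
  obj <- yaml::read_yaml(path)
  for (key in c("inputs", "intervention", "comparator")) {
    if (is.null(obj[[key]])) abort(paste0("config lacks `", key, "` block"))
  }
  de_fit <- function(x) {
    if (is.null(x)) {
      # placeholder replaced by the reconstruction stage (curves pathway)
      return(parametric_fit("exponential", c(rate = 1)))
    }
    parametric_fit(x$family, unlist(x$params))
  }
  de_arm <- function(a) {
    ae <- if (length(a$ae_profile)) {
      dplyr::bind_rows(lapply(a$ae_profile, tibble::as_tibble))
    }
    arm_spec(a$name, de_fit(a$os_fit), de_fit(a$pfs_fit),
             a$drug_cost_per_cycle, ae_profile = ae)
  }
  inputs <- do.call(economic_inputs, obj$inputs)
  params <- if (length(obj$params)) {
    dplyr::bind_rows(lapply(obj$params, tibble::as_tibble))
  }
  ce_config(inputs, de_arm(obj$intervention), de_arm(obj$comparator),
            params = params, curves = obj$curves)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages reconstruct -> fit -> select -> base case ->
#' one-way SA -> PSA -> CEAC and writes every artifact plus a run manifest
#' to `out_dir`. When the configuration supplies pre-fitted survival
#' parameters and no digitized curves, the reconstruction and fitting
#' stages are skipped (the published-parameter pathway). When
#' `config$curves` lists digitized-curve CSVs, each arm/endpoint is
#' reconstructed to pseudo-IPD, all seven families are fitted, the best by
#' AIC/BIC is selected and replaces that arm's fit.
#'
#' `config$curves` is a list of entries `list(arm =, endpoint =,
#' coords_path =, risk_path =, total_events =)` (the tibble returned by
#' [make_fixtures()] also works, row-wise).
#'
#' @param config A [ce_config()] object or path to a YAML configuration.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the PSA.
#' @param n_draws PSA iterations.
#' @param wtp_grid CEAC willingness-to-pay grid.
#' @param stages Stages to run after any reconstruction; subset of
#'   `c("base_case", "owsa", "psa", "ceac")`.
#' @return The run manifest (list), invisibly: config hash, seed, stages
#'   executed, selected families, output paths, package version,
#'   timestamps.
#' @export
run_analysis <- function(config, out_dir, seed = 20240718, n_draws = 5000,
                         wtp_grid = seq(0, 600000, by = 10000),
                         stages = c("base_case", "owsa", "psa", "ceac")) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "ce_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    package = "psmcea",
    version = as.character(packageVersion("psmcea")),
    config_hash = rlang::hash(unclass(config)),
    seed = as.integer(seed),
    n_draws = as.integer(n_draws),
    started = format(Sys.time(), tz = "UTC"),
    stages = character(0),
    selected_families = list(),
    outputs = character(0)
  )
  emit <- function(path) {
    manifest$outputs <<- c(manifest$outputs, path)
    path
  }
  finish <- function(status) {
    manifest$status <<- status
    manifest$finished <<- format(Sys.time(), tz = "UTC")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest
  }

  run_stages <- function() {
    if (!is.null(config$curves)) {
      curves <- config$curves
      if (is.data.frame(curves)) {
        curves <- lapply(seq_len(nrow(curves)), function(i) as.list(curves[i, ]))
      }
      for (cv in curves) {
        curve <- read_digitized_curve(
          cv$coords_path, cv$risk_path, arm_label = cv$arm,
          endpoint = cv$endpoint, total_events = cv$total_events
        )
        ipd <- reconstruct_ipd(curve)
        stem <- file.path(out_dir, paste0(cv$arm, "_", tolower(cv$endpoint)))
        write.csv(ipd, emit(paste0(stem, "_ipd.csv")), row.names = FALSE)
        fits <- fit_all_families(ipd)
        best <- select_best(fits)
        tab <- fit_table(fits)
        tab$params <- vapply(tab$params, function(p) {
          paste(names(p), signif(p, 8), sep = "=", collapse = ";")
        }, character(1))
        write.csv(tab, emit(paste0(stem, "_fits.csv")), row.names = FALSE)
        slot <- if (config$intervention$name == cv$arm) "intervention"
                else "comparator"
        field <- if (toupper(cv$endpoint) == "OS") "os_fit" else "pfs_fit"
        config[[slot]][[field]] <<- fits[[best]]
        manifest$selected_families[[paste0(cv$arm, ".", tolower(cv$endpoint))]] <<- best
      }
      manifest$stages <<- c(manifest$stages, "reconstruct", "fit", "select")
    }

    base <- NULL
    if ("base_case" %in% stages) {
      base <- run_base_case(config)
      for (nm in names(base$traces)) {
        tr <- base$traces[[nm]]
        write.csv(tr, emit(file.path(out_dir, paste0("trace_", nm, ".csv"))),
                  row.names = FALSE)
      }
      summary <- list(
        arms = lapply(seq_len(nrow(base$outcomes)), function(i) {
          as.list(base$outcomes[i, ])
        }),
        incremental = as.list(base$icer[1, ]),
        wtp_threshold = config$inputs$wtp_threshold
      )
      jsonlite::write_json(summary, emit(file.path(out_dir, "summary.json")),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      manifest$stages <<- c(manifest$stages, "base_case")
    }
    if ("owsa" %in% stages) {
      tor <- one_way_sa(config)
      write.csv(tor, emit(file.path(out_dir, "tornado.csv")),
                row.names = FALSE)
      manifest$stages <<- c(manifest$stages, "owsa")
    }
    psa <- NULL
    if ("psa" %in% stages) {
      psa <- run_psa(config, n_draws = n_draws, seed = seed)
      write.csv(psa$draws, emit(file.path(out_dir, "psa_draws.csv")),
                row.names = FALSE)
      manifest$stages <<- c(manifest$stages, "psa")
    }
    if ("ceac" %in% stages && !is.null(psa)) {
      cc <- ceac(psa, wtp_grid)
      write.csv(cc, emit(file.path(out_dir, "ceac.csv")), row.names = FALSE)
      manifest$stages <<- c(manifest$stages, "ceac")
    }
  }

  res <- tryCatch({ run_stages(); NULL }, error = function(e) e)
  if (!is.null(res)) {
    manifest$error <- conditionMessage(res)
    finish("partial")
    abort(paste0("pipeline stage failed: ", conditionMessage(res)))
  }
  invisible(finish("complete"))
}
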