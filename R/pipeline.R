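#' Configuration of a full analysis run
#'
#' Bundles everything a full replication run needs. The defaults are the
#' study's reference configuration: inclusion years 2017 (pre-pandemic)
#' and 2019 (pandemic), 10000 bootstrap resamples, loess span 0.17, 99.9%
#' confidence band, analysis window starting 2020-W11, the seven inclusion
#' codes and five analysis codes, and all six strata (overall, gender, age
#' group).
#'
#' @param consultations,population Paths to registry files, or the
#'   corresponding tibbles ([read_consultations()] / [read_population()]).
#' @param outdir Output directory for tables, figures and the manifest.
#' @param pre_inclusion_year,pan_inclusion_year Inclusion years of the two
#'   datasets.
#' @param codes A [code_set()].
#' @param strata List of [stratum()] objects (default [default_strata()]).
#' @param n_boot Bootstrap resamples per correlation.
#' @param span Loess span.
#' @param ci_level Confidence-band level.
#' @param window_start `c(iso_year, iso_week)` start of the analysis
#'   window.
#' @param seed Integer base seed for all bootstrap draws.
#' @param restriction_periods Tibble `start_year, start_week, end_year,
#'   end_week` of strict social-distancing periods, used only for figure
#'   shading. The default approximates Norway's spring-2020 and
#'   winter/spring-2021 strict periods and is illustrative, not an
#'   authoritative record.
#' @param make_figures Write one figure per diagnosis/stratum (default
#'   TRUE).
#' @return An object of class `run_config`.
#' @export
run_config <- function(consultations, population, outdir,
                       pre_inclusion_year = 2017L, pan_inclusion_year = 2019L,
                       codes = code_set(), strata = default_strata(),
                       n_boot = 10000L, span = 0.17, ci_level = 0.999,
                       window_start = c(2020L, 11L), seed = 1L,
                       restriction_periods = default_restriction_periods(),
                       make_figures = TRUE) {
  structure(
    list(
      consultations = consultations, population = population, outdir = outdir,
      pre_inclusion_year = as.integer(pre_inclusion_year),
      pan_inclusion_year = as.integer(pan_inclusion_year),
      codes = codes, strata = strata, n_boot = as.integer(n_boot),
      span = span, ci_level = ci_level,
      window_start = as.integer(window_start), seed = as.integer(seed),
      restriction_periods = restriction_periods, make_figures = make_figures
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @export
default_restriction_periods <- function() {
  # Illustrative approximation of Norway's strict social-distancing periods.
  tibble::tibble(
    start_year = c(2020L, 2021L), start_week = c(11L, 1L),
    end_year = c(2020L, 2021L), end_week = c(19L, 16L)
  )
}

#' Run the full observed-versus-forecast analysis
#'
#' Reads (or accepts) the registry extracts, builds the pre-pandemic and
#' pandemic analysis datasets, and for every diagnosis-stratum
#' combination estimates the bootstrap correlations, forecasts the two
#' pandemic years, and compares observed with forecast counts. Writes
#' `comparison.csv`, `periods.csv`, `summary.csv`, `forecast.csv`, dataset
#' manifests, a run manifest (`manifest.json`, with config hash and seeds)
#' and optionally one figure per combination. Strata whose weekly series
#' are constant in a required year (correlation undefined, e.g. a
#' near-empty stratum) are recorded as skipped in the summary rather than
#' aborting the run. Any other stage error aborts with the stage name, and
#' partial outputs are removed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the two datasets, the per-combination
#'   `comparison_result`s, the summary tibble, and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  created <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(created), add = TRUE)
  emit <- function(name) {
    p <- file.path(outdir, name)
    created <<- c(created, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  cons <- stage(
    "read consultations",
    if (is.character(config$consultations)) {
      read_consultations(config$consultations)
    } else {
      config$consultations
    }
  )
  pop <- stage(
    "read population",
    if (is.character(config$population)) {
      read_population(config$population)
    } else {
      config$population
    }
  )
  message(sprintf("Input: %d consultations, %d patients", nrow(cons), nrow(pop)))

  pre_ds <- stage("build pre-pandemic dataset", build_dataset(
    cons, pop, cohort_spec(config$pre_inclusion_year, codes = config$codes),
    label = "pre_pandemic"
  ))
  pan_ds <- stage("build pandemic dataset", build_dataset(
    cons, pop, cohort_spec(config$pan_inclusion_year, codes = config$codes),
    label = "pandemic"
  ))
  for (ds in list(pre_ds, pan_ds)) {
    message(sprintf(
      "  %s: cohort %d, retained %d consultations (%d patients)",
      ds$label, length(ds$cohort_ids), ds$n_consultations, ds$n_unique_patients
    ))
    stage("write manifest", write_dataset_manifest(
      ds, emit(sprintf("dataset_%s.json", ds$label))
    ))
  }

  combos <- expand.grid(
    diagnosis = config$codes$analysis_codes,
    stratum_i = seq_along(config$strata),
    stringsAsFactors = FALSE
  )
  results <- list()
  forecasts <- list()
  summary_rows <- list()
  for (i in seq_len(nrow(combos))) {
    diag <- combos$diagnosis[i]
    strat <- config$strata[[combos$stratum_i[i]]]
    label <- paste(diag, format(strat), sep = " / ")
    seed_i <- config$seed + 10L * i
    res <- tryCatch(
      {
        fc <- fit_forecasts(pre_ds, pan_ds, diag,
          strat = strat,
          n_boot = config$n_boot, seed = seed_i
        )
        observed <- slice_years(
          weekly_counts(pan_ds, diag, strat),
          pan_ds$spec$follow_years
        )
        cmp <- compare_to_forecast(observed, fc$first, fc$second,
          window_start = config$window_start,
          span = config$span, level = config$ci_level
        )
        list(cmp = cmp, fc = fc)
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      message("  skipped ", label, ": ", conditionMessage(res))
      summary_rows[[i]] <- tibble::tibble(
        diagnosis = diag, stratum = format(strat),
        mean_deviation_pct = NA_real_, r_mean_first = NA_real_,
        r_mean_second = NA_real_, n_significant_weeks = NA_integer_,
        skipped = conditionMessage(res)
      )
      next
    }
    message(sprintf(
      "  %s: mean deviation %.1f%% (r %0.3f / %0.3f)", label,
      res$cmp$mean_deviation_pct,
      res$cmp$estimates$first$r_mean, res$cmp$estimates$second$r_mean
    ))
    results[[label]] <- res$cmp
    forecasts <- c(forecasts, list(res$fc$first, res$fc$second))
    summary_rows[[i]] <- tibble::tibble(
      diagnosis = diag, stratum = format(strat),
      mean_deviation_pct = res$cmp$mean_deviation_pct,
      r_mean_first = res$cmp$estimates$first$r_mean,
      r_mean_second = res$cmp$estimates$second$r_mean,
      n_significant_weeks = sum(res$cmp$table$flag != "none"),
      skipped = NA_character_
    )
    if (isTRUE(config$make_figures)) {
      fig <- plot_comparison(res$cmp, config$restriction_periods)
      fname <- emit(sprintf("fig_%s_%s.pdf", diag, gsub("[^a-zA-Z0-9]", "_", format(strat))))
      suppressMessages(ggplot2::ggsave(fname, fig, width = 8, height = 4.5))
    }
  }

  comparison <- dplyr::bind_rows(lapply(names(results), function(nm) {
    r <- results[[nm]]
    dplyr::mutate(r$table,
      diagnosis = r$diagnosis, stratum = format(r$stratum),
      .before = 1
    )
  }))
  periods <- dplyr::bind_rows(lapply(names(results), function(nm) {
    r <- results[[nm]]
    if (nrow(r$periods) == 0) {
      return(NULL)
    }
    dplyr::mutate(r$periods,
      diagnosis = r$diagnosis, stratum = format(r$stratum),
      .before = 1
    )
  }))
  summary <- dplyr::bind_rows(summary_rows)

  readr::write_csv(comparison, emit("comparison.csv"))
  readr::write_csv(periods, emit("periods.csv"))
  readr::write_csv(summary, emit("summary.csv"))
  write_forecasts(forecasts, emit("forecast.csv"))
  write_run_manifest(config, emit("manifest.json"))
  ok <- TRUE
  invisible(list(
    pre_dataset = pre_ds, pan_dataset = pan_ds,
    results = results, summary = summary, outdir = outdir
  ))
}

write_run_manifest <- function(config, path) {
  cfg <- list(
    pre_inclusion_year = config$pre_inclusion_year,
    pan_inclusion_year = config$pan_inclusion_year,
    inclusion_codes = config$codes$inclusion_codes,
    analysis_codes = config$codes$analysis_codes,
    strata = vapply(config$strata, format, character(1)),
    n_boot = config$n_boot, span = config$span, ci_level = config$ci_level,
    window_start = config$window_start, seed = config$seed
  )
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- c(cfg, list(
    config_md5 = unname(tools::md5sum(tmp)),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("mhconsult"))
  ))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Plot observed versus forecast weekly counts
#'
#' One time-series panel: observed counts as a solid red line, forecast as
#' a dashed blue line, the 99.9% pointwise band in grey, and strict
#' social-distancing periods shaded light blue.
#'
#' @param result A [compare_to_forecast()] result.
#' @param restriction_periods Optional tibble as in [run_config()]; `NULL`
#'   drops the shading layer.
#' @return A ggplot object.
#' @export
plot_comparison <- function(result, restriction_periods = NULL) {
  stopifnot(inherits(result, "comparison_result"))
  tab <- result$table
  if (nrow(tab) == 0) stop("Empty comparison result.", call. = FALSE)
  year_starts <- tab[tab$iso_week == 1 | seq_len(nrow(tab)) == 1, ]

  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$week_index))
  if (!is.null(restriction_periods) && nrow(restriction_periods) > 0) {
    shade <- restriction_periods
    origin <- min(tab$iso_year)
    shade$xmin <- week_index(shade$start_year, shade$start_week, origin)
    shade$xmax <- week_index(shade$end_year, shade$end_week, origin)
    shade <- shade[shade$xmax >= min(tab$week_index) & shade$xmin <= max(tab$week_index), ]
    if (nrow(shade) > 0) {
      p <- p + ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(
          xmin = pmax(.data$xmin, min(tab$week_index)),
          xmax = pmin(.data$xmax, max(tab$week_index)),
          ymin = -Inf, ymax = Inf
        ),
        inherit.aes = FALSE, fill = "#c6dbef", alpha = 0.5
      )
    }
  }
  p +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      fill = "grey70", alpha = 0.6
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$pred_smooth, colour = "forecast"),
      linetype = "dashed", linewidth = 0.7
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$obs_smooth, colour = "observed"),
      linewidth = 0.7
    ) +
    ggplot2::scale_colour_manual(
      NULL,
      values = c(observed = "#d7301f", forecast = "#2b6cb3")
    ) +
    ggplot2::scale_x_continuous(
      breaks = year_starts$week_index,
      labels = sprintf("%d-W%02d", year_starts$iso_year, year_starts$iso_week)
    ) +
    ggplot2::labs(
      x = "ISO week", y = "Consultations per week",
      title = sprintf(
        "%s, %s: mean deviation %.0f%%",
        result$diagnosis, format(result$stratum), result$mean_deviation_pct
      )
    ) +
    ggplot2::theme_minimal()
}

#' Read a run configuration from YAML
#'
#' Thin convenience loader: reads a YAML file whose keys mirror the
#' [run_config()] arguments (paths, years, `n_boot`, `span`, `ci_level`,
#' `window_start`, `seed`).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("Package 'yaml' is required to read YAML configs.", call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}
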