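#' Simulate a multi-person demo epoch stream
#'
#' Convenience wrapper around [simulate_epoch_stream()]: each person-day gets
#' a wear block of roughly 11-13 h starting around 07:00, partitioned into
#' alternating sedentary (low cpm) and active (high cpm) bouts; remaining
#' minutes are device-off. Useful as packaged demo input for the
#' preprocessing chain.
#'
#' @param n_persons Number of persons (default 6).
#' @param n_days Days per person (default 7).
#' @param seed Integer seed.
#' @param start_date First calendar day (default Monday 2022-01-03).
#' @returns List with `epochs` (all persons), `truth` (wear ground truth) and
#'   `survey` (person-level NRS predictors).
#' @export
simulate_demo_epochs <- function(n_persons = 6, n_days = 7, seed = 1L,
                                 start_date = as.Date("2022-01-03")) {
  set.seed(seed)
  streams <- vector("list", n_persons)
  for (i in seq_len(n_persons)) {
    bouts <- list()
    for (d in seq_len(n_days)) {
      start <- round(rnorm(1, 420, 20))
      wear <- round(rnorm(1, 710, 80))
      wear <- max(520, min(wear, 1439 - start))
      pos <- start
      while (pos < start + wear) {
        len <- min(round(runif(1, 30, 120)), start + wear - pos)
        level <- if (runif(1) < 0.65) 40 else 400 # sedentary vs active bout
        bouts[[length(bouts) + 1]] <-
          tibble(day = d, start = pos, end = pos + len, level = level)
        pos <- pos + len
      }
    }
    spec <- epoch_sim_spec(
      n_days = n_days, wear_bouts = dplyr::bind_rows(bouts),
      seed = sample.int(1e6, 1), person_id = sprintf("p%02d", i),
      start_date = start_date
    )
    streams[[i]] <- simulate_epoch_stream(spec)
  }
  draw_nrs_int <- function(n, m, s) pmax(0, pmin(10, round(rnorm(n, m, s))))
  survey <- tibble(
    person_id = sprintf("p%02d", seq_len(n_persons)),
    pain = draw_nrs_int(n_persons, 1.9, 2.4),
    fatigue = draw_nrs_int(n_persons, 3.5, 3.4),
    wellbeing = draw_nrs_int(n_persons, 6.4, 2.4)
  )
  list(
    epochs = dplyr::bind_rows(lapply(streams, `[[`, "epochs")),
    truth = dplyr::bind_rows(lapply(streams, `[[`, "truth")),
    survey = survey
  )
}

#' Run the preprocessing chain from epochs to an analysis panel
#'
#' Collapses 10 s epochs to counts-per-minute if needed, detects non-wear,
#' classifies worn minutes at the intensity cut-point, summarizes days,
#' applies the wear protocol and joins the person-level predictors.
#'
#' @param epochs Epoch tibble (10 s or 60 s resolution).
#' @param survey Tibble `person_id` plus predictor columns.
#' @param min_wear,min_valid_days,require_weekend_days,cutpoint_cpm,min_window_min,allowance_min,low_count_max
#'   Protocol thresholds; defaults are the standard protocol (500 min/day,
#'   4 days incl. 1 weekend day, 100 cpm cut-point, 60 min zero window with a
#'   2 min 0-100 cpm allowance).
#' @returns List with `panel`, `days`, `validity`.
#' @export
run_prep <- function(epochs, survey,
                     min_wear = 500, min_valid_days = 4,
                     require_weekend_days = 1, cutpoint_cpm = 100,
                     min_window_min = 60, allowance_min = 2,
                     low_count_max = 100) {
  step <- infer_epoch_length(epochs)
  minutes <- if (step == 10) collapse_epochs(epochs) else epochs
  days <- minutes |>
    detect_nonwear(
      min_window_min = min_window_min, allowance_min = allowance_min,
      low_count_max = low_count_max
    ) |>
    classify_minutes(cutpoint_cpm = cutpoint_cpm) |>
    summarize_days(min_wear = min_wear)
  validity <- apply_protocol(
    days, min_valid_days = min_valid_days,
    require_weekend_days = require_weekend_days
  )
  panel <- build_panel(days, survey, validity = validity)
  list(panel = panel, days = days, validity = validity)
}

infer_epoch_length <- function(epochs) {
  d <- diff(as.numeric(epochs$timestamp[epochs$person_id == epochs$person_id[1]]))
  step <- unique(d)[1]
  if (!step %in% c(10, 60)) {
    abort(sprintf("Unsupported epoch resolution: %s s.", format(step)))
  }
  step
}

#' Run the full pipeline: prep, fit, report
#'
#' Reads an epoch CSV and a survey CSV, builds the panel, fits the DSEM for
#' one predictor, and writes `panel.csv`, `draws.csv`, `summary.csv`,
#' `descriptives.csv` and `manifest.json` into `out_dir`. Outputs are
#' byte-identical across runs with the same inputs, config and seed.
#'
#' @param epochs_file,survey_file Input CSV paths.
#' @param out_dir Output directory (created if missing).
#' @param predictor Predictor column to model (default `"pain"`).
#' @param config A [fit_config()].
#' @param ... Prep thresholds passed to [run_prep()].
#' @returns Invisibly, a list with `panel`, `fit`, `table`, `descriptives`,
#'   `manifest`.
#' @export
run_pipeline <- function(epochs_file, survey_file, out_dir,
                         predictor = "pain", config = fit_config(), ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  epochs <- read_epochs(epochs_file)
  survey <- readr::read_csv(
    survey_file, col_types = readr::cols(person_id = readr::col_character()),
    na = "", progress = FALSE
  )
  prep <- run_prep(epochs, survey, ...)
  write_panel(prep$panel, file.path(out_dir, "panel.csv"))
  fit <- dsem_fit(prep$panel, predictor = predictor, config = config)
  write_draws(fit, file.path(out_dir, "draws.csv"))
  tab <- dsem_table(fit)
  write_summary(tab, file.path(out_dir, "summary.csv"))
  desc <- descriptives(prep$panel)
  write_summary(desc, file.path(out_dir, "descriptives.csv"))
  conv <- psr(fit)
  manifest <- list(
    tool = "actidsem", version = as.character(utils::packageVersion("actidsem")),
    inputs = list(
      epochs = basename(epochs_file), survey = basename(survey_file),
      n_epoch_rows = nrow(epochs), n_survey_rows = nrow(survey)
    ),
    predictor = predictor,
    config = config[c("iterations", "thin", "chains", "burn_in_fraction", "seed")],
    exclusions = as.list(stats::setNames(
      !prep$validity$included, prep$validity$person_id
    )),
    n_included = sum(prep$validity$included),
    n_panel_rows = nrow(prep$panel),
    max_psr = max(conv$psr),
    lambda_accept_mean = mean(vapply(
      fit$chains, function(ch) mean(ch$lambda_accept), 0
    )),
    outputs = c("panel.csv", "draws.csv", "summary.csv", "descriptives.csv")
  )
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(
    panel = prep$panel, fit = fit, table = tab, descriptives = desc,
    manifest = manifest
  ))
}

cli_usage <- function() {
  paste(
    "usage: actidsem <subcommand> [--flag value ...]",
    "",
    "subcommands:",
    "  simulate-epochs --out DIR [--persons N] [--days D] [--seed S]",
    "  simulate-panel  --out FILE [--persons N] [--days D] [--missing P] [--seed S]",
    "  prep            --epochs FILE --survey FILE --out DIR",
    "  fit             --panel FILE --out DIR [--predictor pain] [--iterations I]",
    "                  [--thin T] [--chains C] [--seed S]",
    "  report          --panel FILE --out DIR",
    "  pipeline        --epochs FILE --survey FILE --out DIR [--predictor pain]",
    "                  [--iterations I] [--thin T] [--chains C] [--seed S]",
    sep = "\n"
  )
}

parse_cli_flags <- function(args, allowed) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--") || i == length(args)) {
      return(structure(list(), error = paste0("Unexpected argument: ", a)))
    }
    key <- sub("^--", "", a)
    if (!key %in% allowed) {
      return(structure(list(), error = paste0("Unknown flag: --", key)))
    }
    flags[[key]] <- args[i + 1]
    i <- i + 2
  }
  flags
}

flag_int <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.integer(flags[[key]])
}

#' Command-line entry point
#'
#' Thin argv-based dispatcher over the package functions; see
#' `inst/cli/actidsem` for the Rscript wrapper. Subcommands:
#' `simulate-epochs`, `simulate-panel`, `prep`, `fit`, `report`, `pipeline`.
#' Every run writes a JSON manifest next to its outputs. Unknown subcommands
#' or flags print usage and return a non-zero status.
#'
#' @param args Character vector of command-line arguments.
#' @returns Integer exit status, invisibly (0 = success).
#' @export
dsem_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message(cli_usage())
    return(invisible(1L))
  }
  sub <- args[1]
  rest <- args[-1]
  subs <- c("simulate-epochs", "simulate-panel", "prep", "fit", "report", "pipeline")
  if (!sub %in% subs) {
    message("Unknown subcommand: ", sub, "\n", cli_usage())
    return(invisible(1L))
  }
  allowed <- c(
    "out", "persons", "days", "seed", "missing", "epochs", "survey",
    "panel", "predictor", "iterations", "thin", "chains"
  )
  flags <- parse_cli_flags(rest, allowed)
  if (!is.null(attr(flags, "error"))) {
    message(attr(flags, "error"), "\n", cli_usage())
    return(invisible(1L))
  }
  status <- tryCatch({
    switch(sub,
      "simulate-epochs" = {
        dir.create(flags$out, recursive = TRUE, showWarnings = FALSE)
        sim <- simulate_demo_epochs(
          n_persons = flag_int(flags, "persons", 6L),
          n_days = flag_int(flags, "days", 7L),
          seed = flag_int(flags, "seed", 1L)
        )
        write_epochs(sim$epochs, file.path(flags$out, "epochs.csv"))
        readr::write_csv(sim$survey, file.path(flags$out, "survey.csv"), na = "")
        readr::write_csv(sim$truth, file.path(flags$out, "wear_truth.csv"), na = "")
        write_manifest(
          list(
            tool = "actidsem", subcommand = sub,
            seed = flag_int(flags, "seed", 1L),
            n_persons = flag_int(flags, "persons", 6L),
            n_rows = nrow(sim$epochs)
          ),
          file.path(flags$out, "manifest.json")
        )
        0L
      },
      "simulate-panel" = {
        spec <- panel_sim_spec(
          n_persons = flag_int(flags, "persons", 41L),
          t_days = flag_int(flags, "days", 7L),
          missing_day_prob = if (is.null(flags$missing)) 0 else as.numeric(flags$missing),
          seed = flag_int(flags, "seed", 1L)
        )
        sim <- simulate_panel(spec)
        write_panel(sim$panel, flags$out)
        readr::write_csv(
          sim$effects, paste0(sub("\\.csv$", "", flags$out), "_truth.csv"),
          na = ""
        )
        0L
      },
      "prep" = {
        dir.create(flags$out, recursive = TRUE, showWarnings = FALSE)
        epochs <- read_epochs(flags$epochs)
        survey <- readr::read_csv(
          flags$survey,
          col_types = readr::cols(person_id = readr::col_character()),
          na = "", progress = FALSE
        )
        prep <- run_prep(epochs, survey)
        write_panel(prep$panel, file.path(flags$out, "panel.csv"))
        write_manifest(
          list(
            tool = "actidsem", subcommand = sub,
            n_epoch_rows = nrow(epochs),
            exclusions = as.list(stats::setNames(
              !prep$validity$included, prep$validity$person_id
            )),
            exclusion_reason = "wear protocol: < 4 valid days (>= 500 wear min) incl. 1 weekend day",
            n_included = sum(prep$validity$included),
            n_panel_rows = nrow(prep$panel)
          ),
          file.path(flags$out, "manifest.json")
        )
        0L
      },
      "fit" = {
        dir.create(flags$out, recursive = TRUE, showWarnings = FALSE)
        panel <- read_panel(flags$panel)
        cfg <- fit_config(
          iterations = flag_int(flags, "iterations", 50000L),
          thin = flag_int(flags, "thin", 10L),
          chains = flag_int(flags, "chains", 2L),
          seed = flag_int(flags, "seed", 1L)
        )
        fit <- dsem_fit(panel, predictor = flags$predictor %||% "pain", config = cfg)
        write_draws(fit, file.path(flags$out, "draws.csv"))
        write_summary(dsem_table(fit), file.path(flags$out, "summary.csv"))
        conv <- psr(fit)
        write_manifest(
          list(
            tool = "actidsem", subcommand = sub,
            predictor = flags$predictor %||% "pain",
            config = cfg[c("iterations", "thin", "chains", "seed")],
            max_psr = max(conv$psr)
          ),
          file.path(flags$out, "manifest.json")
        )
        0L
      },
      "report" = {
        dir.create(flags$out, recursive = TRUE, showWarnings = FALSE)
        panel <- read_panel(flags$panel)
        write_summary(descriptives(panel), file.path(flags$out, "descriptives.csv"))
        write_manifest(
          list(tool = "actidsem", subcommand = sub, n_panel_rows = nrow(panel)),
          file.path(flags$out, "manifest.json")
        )
        0L
      },
      "pipeline" = {
        cfg <- fit_config(
          iterations = flag_int(flags, "iterations", 50000L),
          thin = flag_int(flags, "thin", 10L),
          chains = flag_int(flags, "chains", 2L),
          seed = flag_int(flags, "seed", 1L)
        )
        run_pipeline(
          flags$epochs, flags$survey, flags$out,
          predictor = flags$predictor %||% "pain", config = cfg
        )
        0L
      }
    )
  }, error = function(e) {
    message("Error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
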