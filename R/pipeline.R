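# End-to-end orchestration: read corpus and reference tables, fill in
# polarity (or accept supplied labels), tag topics, impute race, compute
# daily engagement and net-sentiment scores per stratification, weekly
# sentiment averages, and per-sub-period five-number summaries; write
# everything as plain CSV/JSON plus a run manifest. Outputs are staged in
# a temporary directory and only copied into place on success, so a failed
# run never leaves partial files.

pipeline_defaults <- function() {
  list(
    format = "auto",
    lexicon = NULL,                 # NULL -> packaged default lexicon
    beta = 0.725,
    window_days = 7,
    prior_weight = 1 / 7,
    prior_base = 1,
    level = 0.95,
    n_mc = 20000,
    seed_race = 20201001,
    seed_pss = 20210521,
    stratifications = c("nation", "state", "race", "topic"),
    period_boundaries = format(default_period_boundaries(), "%Y-%m-%d"),
    study_start = NULL,
    study_end = NULL,
    classifier_model = NULL,
    case_series = NULL,
    vaccination_series = NULL,
    per_surname = FALSE
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    base_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    # resolve relative paths against the config file location
    path_keys <- c("corpus", "population_table", "race_population_table",
                   "surname_table", "lexicon", "classifier_model",
                   "case_series", "vaccination_series", "out_dir")
    for (key in intersect(path_keys, names(config))) {
      if (is.character(config[[key]]) && nzchar(config[[key]]) &&
          !grepl("^(/|[A-Za-z]:)", config[[key]])) {
        config[[key]] <- file.path(base_dir, config[[key]])
      }
    }
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  need <- c("corpus", "population_table", "race_population_table",
            "surname_table")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys)) {
    stop("pipeline config lacks key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  cfg
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full social-sensing pipeline
#'
#' Executes every analysis stage on a corpus and writes the score tables:
#' daily PES per stratification (`pes_<stratification>.csv`), daily net
#' sentiment with credible intervals (`pss_daily_<stratification>.csv`),
#' weekly sentiment averages (`pss_weekly.csv`), per-sub-period
#' five-number summaries (`quartiles_pes.csv`, `quartiles_pss.csv`), the
#' race classification-rate summary (`race_summary.json`), optional
#' aligned daily case/vaccination series, and a run manifest
#' (`manifest.json`) recording every parameter and seed. Given fixed
#' seeds, reruns are byte-identical except for the manifest timestamp.
#'
#' If the corpus lacks polarity labels, a serialized Naive Bayes model
#' (`classifier_model` key) is required to fill them in; supplying labels
#' on input is the recommended mode.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Mandatory keys: `corpus`, `population_table` (state
#'   populations, optional `nation` row), `race_population_table`,
#'   `surname_table`. Optional keys with defaults: `lexicon`, `beta`
#'   (0.725), `window_days` (7), `prior_weight` (1/7), `prior_base` (1),
#'   `level` (0.95), `n_mc` (20000), `seed_race`, `seed_pss`,
#'   `stratifications`, `period_boundaries`, `study_start`/`study_end`,
#'   `classifier_model`, `case_series`, `vaccination_series`,
#'   `per_surname`.
#' @param out_dir Output directory (created; may also be given as the
#'   config key `out_dir`).
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_pipeline_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("no output directory given", call. = FALSE)

  stage_dir <- tempfile("opinionpulse_run_")
  dir.create(stage_dir)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)
  emit <- function(df, name) write_daily_scores(df, file.path(stage_dir, name))

  tweets <- pipeline_stage("read_corpus", {
    tw <- read_tweets(cfg$corpus, format = cfg$format)
    err <- parse_errors(tw)
    message("read_corpus: ", nrow(tw), " records, ", nrow(err), " skipped")
    tw
  })
  n_skipped <- nrow(parse_errors(tweets))
  populations <- pipeline_stage("read_tables",
    read_population_table(cfg$population_table))
  race_pop <- pipeline_stage("read_tables",
    read_population_table(cfg$race_population_table))
  surname_table <- pipeline_stage("read_tables",
    read_surname_table(cfg$surname_table))
  lexicon <- pipeline_stage("read_tables", {
    if (is.null(cfg$lexicon)) default_lexicon() else read_lexicon(cfg$lexicon)
  })

  dates <- pipeline_stage("study_window", {
    start <- if (is.null(cfg$study_start)) min(tweets$tweet_date) else
      as.Date(cfg$study_start)
    end <- if (is.null(cfg$study_end)) max(tweets$tweet_date) else
      as.Date(cfg$study_end)
    outside <- tweets$tweet_date < start | tweets$tweet_date > end
    if (any(outside)) {
      stop(sum(outside), " record(s) outside the study window, first id ",
           tweets$message_id[which(outside)[1L]])
    }
    seq(start, end, by = "day")
  })
  boundaries <- as.Date(unlist(cfg$period_boundaries))

  tweets <- pipeline_stage("polarity", {
    missing_pol <- is.na(tweets$polarity)
    if (any(missing_pol)) {
      if (is.null(cfg$classifier_model)) {
        stop(sum(missing_pol), " record(s) lack polarity and no ",
             "classifier_model is configured")
      }
      model <- read_nb_model(cfg$classifier_model)
      pred <- classify_all(model, tweets$tweet_text[missing_pol])
      tweets$polarity[missing_pol] <- pred$polarity
      message("polarity: classified ", sum(missing_pol), " records")
    } else {
      message("polarity: labels supplied for all ", nrow(tweets), " records")
    }
    bad <- !tweets$polarity %in% POLARITY_LEVELS
    if (any(bad)) stop("invalid polarity label(s): ",
                       paste(unique(tweets$polarity[bad]), collapse = ", "))
    tweets
  })

  tweets <- pipeline_stage("topics", {
    tw <- annotate_topics(tweets, lexicon)
    message("topics: ", sum(!is.na(tw$topics)), " of ", nrow(tw),
            " records tagged")
    tw
  })

  annotated <- pipeline_stage("race", {
    ann <- annotate_corpus(tweets, surname_table, seed = cfg$seed_race,
                           per_surname = isTRUE(cfg$per_surname))
    message("race: matched fraction ",
            sprintf("%.3f", ann$summary$matched_fraction))
    ann
  })
  tweets <- annotated$tweets
  race_summary <- annotated$summary

  strats <- intersect(c("nation", "state", "race", "topic"),
                      unlist(cfg$stratifications))
  pes_tables <- pipeline_stage("engagement", {
    tabs <- lapply(setNames(strats, strats), function(s) {
      pop <- if (s == "race") race_pop else populations
      pes <- daily_pes(tweets, pop, stratify_by = s, beta = cfg$beta,
                       dense_grid = TRUE, dates = dates)
      emit(pes, paste0("pes_", s, ".csv"))
      pes
    })
    message("engagement: PES for ", paste(strats, collapse = ", "))
    tabs
  })

  pss_tables <- pipeline_stage("sentiment", {
    tabs <- lapply(setNames(strats, strats), function(s) {
      counts <- count_polarities(tweets, stratify_by = s, dates = dates)
      pss <- daily_pss_series(counts, window_days = cfg$window_days,
                              prior_weight = cfg$prior_weight,
                              base = cfg$prior_base, level = cfg$level,
                              n_mc = cfg$n_mc, seed = cfg$seed_pss)
      emit(pss, paste0("pss_daily_", s, ".csv"))
      pss
    })
    message("sentiment: PSS for ", paste(strats, collapse = ", "))
    tabs
  })

  pipeline_stage("weekly_and_periods", {
    weekly <- do.call(rbind, lapply(names(pss_tables), function(s) {
      w <- weekly_average(pss_tables[[s]])
      cbind(stratification = s, w)
    }))
    emit(weekly, "pss_weekly.csv")
    qp <- do.call(rbind, lapply(names(pes_tables), function(s) {
      cbind(stratification = s,
            period_quartiles(pes_tables[[s]], "pes", boundaries))
    }))
    emit(qp, "quartiles_pes.csv")
    qs <- do.call(rbind, lapply(names(pss_tables), function(s) {
      w <- weekly_average(pss_tables[[s]])
      cbind(stratification = s,
            period_quartiles(w, "pss", boundaries, date_col = "week_start"))
    }))
    emit(qs, "quartiles_pss.csv")
    message("summaries: weekly PSS and per-period quartiles written")
  })

  pipeline_stage("aligned_series", {
    for (key in c("case_series", "vaccination_series")) {
      if (!is.null(cfg[[key]])) {
        s <- read_daily_series(cfg[[key]])
        emit(s, paste0(sub("_series", "", key), "_daily.csv"))
      }
    }
  })

  pipeline_stage("manifest", {
    manifest <- list(
      package = "opinionpulse",
      version = as.character(utils::packageVersion("opinionpulse")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      parameters = cfg[c("beta", "window_days", "prior_weight",
                         "prior_base", "level", "n_mc", "seed_race",
                         "seed_pss", "per_surname")],
      stratifications = strats,
      period_boundaries = format(boundaries, "%Y-%m-%d"),
      study_window = format(range(dates), "%Y-%m-%d"),
      n_records = nrow(tweets),
      n_parse_errors = n_skipped,
      race_summary = race_summary,
      notes = list(
        topic_population = "topic PES uses the national population"
      )
    )
    jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(race_summary,
                         file.path(stage_dir, "race_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  file.copy(dir(stage_dir, full.names = TRUE), out_dir, overwrite = TRUE)
  message("pipeline: ", length(dir(stage_dir)), " artifact(s) -> ", out_dir)
  invisible(out_dir)
}
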