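#' @name io_cli
#' @title Study file formats and pipeline orchestration
#' @description Plain-text study bundles: a TAC TSV (`subject_id`,
#'   `region`, `frame_start_min`, `frame_dur_min`, `activity_kBq_mL`), a
#'   blood TSV per subject (`subject_id`, `time_min`,
#'   `whole_plasma_kBq_mL`, `parent_fraction`), a participant metadata CSV
#'   (`subject_id`, `group`, `age`, `sex`, `scan_date`, `fP`,
#'   `injected_dose`) and an optional `truth.json` ledger. Every file
#'   carries a schema-version header comment. Numeric fields round-trip
#'   at full double precision.
NULL

schema_headers <- c(tacs = "# petpool tacs v1",
                    blood = "# petpool blood v1",
                    participants = "# petpool participants v1")

write_num_table <- function(df, path, header, sep) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- sprintf("%.17g", df[[j]])
  write.table(out, con, sep = sep, row.names = FALSE, quote = FALSE)
}

# blood sampling times used when serializing a continuous input function
blood_sample_times <- function() {
  c(seq(0.25, 3, by = 0.25), 4, 5, 6, 8, 10, 15, 20, 30, 45, 60, 75, 90,
    110)
}

#' Write a study to a directory of plain-text files
#'
#' @param study A `synthetic_study` or study bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tt <- study$tacs
  tac_df <- data.frame(subject_id = tt$subject_id, region = tt$region,
                       frame_start_min = tt$frame_start_min,
                       frame_dur_min = tt$frame_dur_min,
                       activity_kBq_mL = tt$activity)
  write_num_table(tac_df, file.path(dir, "tacs.tsv"),
                  schema_headers["tacs"], "\t")
  ts <- blood_sample_times()
  rows <- lapply(study$participants$subject_id, function(sid) {
    a <- study$aif[[sid]]
    wp <- a$c_wholeplasma(ts)
    cp <- a$cp_parent(ts)
    data.frame(subject_id = sid, time_min = ts,
               whole_plasma_kBq_mL = wp,
               parent_fraction = ifelse(wp > 0, pmin(cp / wp, 1), 1))
  })
  write_num_table(do.call(rbind, rows), file.path(dir, "blood.tsv"),
                  schema_headers["blood"], "\t")
  write_num_table(as.data.frame(study$participants),
                  file.path(dir, "participants.csv"),
                  schema_headers["participants"], ",")
  if (!is.null(study$truth)) {
    truth <- study$truth
    truth$lambda <- list(dim = dim(truth$lambda),
                         dimnames = dimnames(truth$lambda),
                         values = as.vector(truth$lambda))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(file.path(dir, c("tacs.tsv", "blood.tsv",
                             "participants.csv")))
}

read_headed <- function(path, header, sep) {
  first <- readLines(path, n = 1)
  if (!identical(first, unname(header))) {
    stop("unrecognized schema header in ", basename(path), ": ", first)
  }
  read.delim(path, sep = sep, skip = 1, header = TRUE,
             stringsAsFactors = FALSE)
}

#' Read a study bundle from a directory
#'
#' Validates the files against their schemas: every TAC subject must be
#' present in the metadata, blood sample times must be strictly
#' increasing per subject, and frame schedules must be consistent across
#' subjects. Violations raise itemized errors.
#'
#' @param dir Directory holding `tacs.tsv`, `blood.tsv`,
#'   `participants.csv` and optionally `truth.json`.
#' @return A `study_bundle` usable by the fitting functions: elements
#'   `participants`, `tacs`, `aif`, `schedule`, `truth` (or `NULL`),
#'   `config` (region roles inferred from the data).
#' @export
read_study <- function(dir) {
  tacs <- read_headed(file.path(dir, "tacs.tsv"),
                      schema_headers["tacs"], "\t")
  blood <- read_headed(file.path(dir, "blood.tsv"),
                       schema_headers["blood"], "\t")
  part <- read_headed(file.path(dir, "participants.csv"),
                      schema_headers["participants"], ",")
  missing <- setdiff(unique(tacs$subject_id), part$subject_id)
  if (length(missing)) {
    stop("subjects in TACs missing from metadata: ",
         paste(missing, collapse = ", "))
  }
  key0 <- tacs[tacs$subject_id == tacs$subject_id[1] &
                 tacs$region == tacs$region[1], ]
  sched <- frame_schedule(key0$frame_start_min, key0$frame_dur_min)
  aif <- list()
  for (sid in part$subject_id) {
    b <- blood[blood$subject_id == sid, ]
    if (nrow(b) == 0) next
    bad <- which(diff(b$time_min) <= 0)
    if (length(bad)) {
      stop("non-monotone blood sample times for ", sid, " at row ",
           bad[1] + 1)
    }
    bd <- blood_data(b$time_min, b$whole_plasma_kBq_mL,
                     b$parent_fraction)
    fp <- part$fP[part$subject_id == sid]
    aif[[sid]] <- arterial_input_from_blood(bd, fp)
  }
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
    if (!is.null(truth$lambda)) {
      truth$lambda <- array(truth$lambda$values, unlist(truth$lambda$dim),
                            truth$lambda$dimnames)
    }
  }
  tac_tab <- tibble::tibble(
    subject_id = tacs$subject_id, region = tacs$region,
    frame = stats::ave(tacs$frame_start_min, tacs$subject_id,
                       tacs$region, FUN = seq_along),
    frame_start_min = tacs$frame_start_min,
    frame_dur_min = tacs$frame_dur_min,
    activity = tacs$activity_kBq_mL)
  regions <- unique(tac_tab$region)
  refs <- intersect(c("CGM", "CWM"), regions)
  structure(list(
    participants = tibble::as_tibble(part), tacs = tac_tab, aif = aif,
    schedule = sched, truth = truth,
    config = list(target_regions = setdiff(regions, refs),
                  rn_region = if ("RN" %in% regions) "RN" else
                    regions[length(regions)],
                  projection_regions = setdiff(regions,
                                               c(refs, "RN")),
                  reference_region = if ("CWM" %in% regions) "CWM" else
                    NULL)),
    class = c("study_bundle"))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a study, runs NLS quantification, the requested
#' hierarchical analyses and the contrast extraction, and writes all
#' artifacts (tables, draws summaries, a run log with seed, config hash
#' and package version) to a directory.
#'
#' @param config A list (or path to a YAML file) with optional blocks
#'   `cohort` (arguments of [cohort_config()]), `mcmc` (arguments of
#'   [mcmc_control()]), `seed`, `methods` (subset of `c("nls", "lme",
#'   "pumba", "simba")`), `outcome`, and `out_dir`.
#' @return Invisibly, a list of artifact paths and key results.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  out_dir <- config$out_dir %||% tempfile("petpool_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cc <- do.call(cohort_config, config$cohort %||% list())
  mc <- do.call(mcmc_control, utils::modifyList(
    list(seed = seed), config$mcmc %||% list()))
  methods <- config$methods %||% c("nls", "lme", "pumba")
  outcome <- config$outcome %||% "bpnd"

  study <- simulate_cohort(cc, seed = seed)
  write_study(study, file.path(out_dir, "study"))
  results <- list()

  log <- list(seed = seed,
              config_hash = sum(utf8ToInt(paste(deparse(config),
                                                collapse = ""))),
              package_version = as.character(
                utils::packageVersion("petpool")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC"))

  nls_2tcm <- NULL
  if (any(c("nls", "lme", "pumba") %in% methods)) {
    nls_2tcm <- fit_cohort_nls(study, "2tcm", variant = outcome,
                               seed = seed)
    write_num_table(as.data.frame(nls_2tcm),
                    file.path(out_dir, "nls_2tcm.csv"),
                    "# petpool nls v1", ",")
    results$nls <- nls_2tcm
  }
  if ("lme" %in% methods) {
    bp_par <- grep("^logBP", unique(nls_2tcm$parameter), value = TRUE)[1]
    bp <- nls_2tcm[nls_2tcm$parameter == bp_par & nls_2tcm$converged, ]
    tab <- merge(bp, as.data.frame(study$participants), by = "subject_id")
    tab$logBP <- tab$estimate_log
    lfit <- fit_univariate_lme(tab)
    ctr <- group_contrasts(lfit)
    write_num_table(as.data.frame(ctr),
                    file.path(out_dir, "contrasts_lme.csv"),
                    "# petpool contrasts v1", ",")
    results$lme <- ctr
  }
  if ("pumba" %in% methods) {
    srtm <- fit_cohort_nls(study, "srtm", seed = seed)
    inp <- pumba_input(srtm, study$participants)
    draws <- fit_pumba(inp, control = mc)
    ctr <- group_contrasts(draws)
    write_draw_summary(draws, file.path(out_dir, "pumba"))
    write_num_table(as.data.frame(ctr),
                    file.path(out_dir, "contrasts_pumba.csv"),
                    "# petpool contrasts v1", ",")
    results$pumba <- ctr
  }
  if ("simba" %in% methods) {
    model <- build_simba_model(study, outcome = outcome)
    draws <- fit_simba(model, mc)
    ctr <- group_contrasts(draws)
    write_draw_summary(draws, file.path(out_dir, "simba"))
    write_num_table(as.data.frame(ctr),
                    file.path(out_dir, "contrasts_simba.csv"),
                    "# petpool contrasts v1", ",")
    results$simba <- ctr
  }
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(c(results, list(out_dir = out_dir, study = study)))
}

#' Persist posterior draws and a JSON summary
#'
#' Writes the scalar draws as a long CSV (`draw`, `parameter`, `value`)
#' and a JSON summary (posterior means, 95% intervals, R-hat).
#'
#' @param draws A `pet_draws`.
#' @param stem Output path stem (writes `<stem>_draws.csv` and
#'   `<stem>_summary.json`).
#' @return Invisibly, the two paths.
#' @export
write_draw_summary <- function(draws, stem) {
  d <- draws$draws
  long <- data.frame(draw = rep(seq_len(nrow(d)), ncol(d)),
                     parameter = rep(colnames(d), each = nrow(d)),
                     value = as.vector(d))
  write_num_table(long, paste0(stem, "_draws.csv"),
                  "# petpool draws v1", ",")
  summ <- lapply(colnames(d), function(nm) {
    list(mean = mean(d[, nm]),
         lo95 = unname(quantile(d[, nm], 0.025)),
         hi95 = unname(quantile(d[, nm], 0.975)),
         rhat = unname(draws$diagnostics$rhat[nm]))
  })
  names(summ) <- colnames(d)
  jsonlite::write_json(summ, paste0(stem, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paste0(stem, "_draws.csv"), paste0(stem, "_summary.json")))
}
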