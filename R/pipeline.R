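#' Read a flat key/value configuration file
#'
#' Accepts an INI-style text file (`key = value` per line, `#` comments) or a
#' JSON object; keys mirror [phantom_params()] / [cohort_params()] argument
#' names. Values that parse as numbers become numeric; `true`/`false` become
#' logical.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("read_config: file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  if (grepl("\\.json$", path) || grepl("^\\s*\\{", paste(txt, collapse = ""))) {
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  txt <- trimws(txt)
  txt <- txt[nzchar(txt) & !startsWith(txt, "#") & !startsWith(txt, ";")]
  kv <- regmatches(txt, regexec("^([^=]+)=(.*)$", txt))
  bad <- which(lengths(kv) != 3L)
  if (length(bad))
    stop("read_config: malformed line ", bad[1L], ": '", txt[bad[1L]], "'",
         call. = FALSE)
  keys <- trimws(vapply(kv, `[`, character(1), 2L))
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  out <- lapply(vals, function(v) {
    if (tolower(v) %in% c("true", "false")) return(as.logical(toupper(v)))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- keys
  out
}

# Digest of a config, stable under key reordering.
config_digest <- function(config) {
  keys <- sort(names(config))
  lines <- vapply(keys, function(k)
    paste0(k, "=", paste(format(config[[k]], digits = 17), collapse = ",")),
    character(1))
  tmp <- tempfile(fileext = ".cfg")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full simulate-summarise-correlate pipeline
#'
#' Generates (or loads) a longitudinal cohort, writes the cohort CSV, group
#' summaries, per-interval change statistics for both structural metrics, the
#' four subject-controlled partial correlations (mean/max IOP versus
#' MRW/LCD over the post-baseline months of the OHT right eyes), and a
#' reproducibility manifest. Identical config and seed give byte-identical
#' output CSVs.
#'
#' @param config Named list (see [read_config()]) overriding
#'   [cohort_params()] arguments; may instead contain `cohort_csv` pointing
#'   at an existing cohort table.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed (overrides `config$seed`).
#' @return Invisibly, a list with the cohort table, the summary data frames
#'   and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  stopifnot(is.list(config))
  if (!is.null(seed)) config$seed <- seed
  param_names <- names(formals(cohort_params))
  unknown <- setdiff(names(config), c(param_names, "cohort_csv"))
  if (length(unknown))
    stop("run_pipeline: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  if (!is.null(config$cohort_csv)) {
    cohort <- read_cohort_csv(config$cohort_csv)
  } else {
    params <- do.call(cohort_params, config[setdiff(names(config), "cohort_csv")])
    cohort <- generate_cohort(params)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))

  # group summaries: structural metrics at baseline and final month, per arm
  last_month <- max(cohort$month)
  arms <- c("oht_right", "oht_left", "control")
  arms <- arms[vapply(arms, function(a) nrow(cohort_arm(cohort, a)) > 0,
                      logical(1))]
  summaries <- do.call(rbind, lapply(arms, function(a) {
    sub <- cohort_arm(cohort, a)
    do.call(rbind, lapply(c("mrw", "lcd", "mean_iop"), function(col) {
      do.call(rbind, lapply(c(0L, last_month), function(m) {
        gs <- group_summary(sub, col, month = m)
        data.frame(arm = a, column = col, month = m, mean = gs$mean,
                   sd = gs$sd, n = gs$n)
      }))
    }))
  }))
  utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE, quote = FALSE)

  changes <- do.call(rbind, lapply(c("mrw", "lcd"), function(metric) {
    ch <- monthly_change(cohort, metric, arm = "oht_right")
    cbind(metric = metric, ch)
  }))
  utils::write.csv(changes, file.path(out_dir, "changes.csv"),
                   row.names = FALSE, quote = FALSE)

  post <- cohort_arm(cohort[cohort$month >= 1L, , drop = FALSE], "oht_right")
  cors <- do.call(rbind, lapply(c("mean_iop", "max_iop"), function(xv) {
    do.call(rbind, lapply(c("mrw", "lcd"), function(yv) {
      pc <- partial_correlation(post[[xv]], post[[yv]], post$primate_id)
      data.frame(x = xv, y = yv, rho = pc$rho_hat, n_obs = pc$n_obs,
                 n_subjects = pc$n_subjects, df = pc$df, z = pc$z_stat,
                 p_value = pc$p_value)
    }))
  }))
  utils::write.csv(cors, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- list(
    command = "run_pipeline",
    config_digest = config_digest(config),
    seed = if (is.null(config$seed)) formals(cohort_params)$seed else config$seed,
    package_version = as.character(utils::packageVersion("onhmorph")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, summaries = summaries, changes = changes,
                 correlations = cors, manifest = manifest))
}
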