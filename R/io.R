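# CSV dialect: comma-separated, UTF-8, "." decimal, mandatory header row,
# metadata as "# key=value" comment lines before the header. Doses in Gy,
# times in hours.

read_csv_with_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (m in lines[is_meta]) {
    m <- sub("^\\s*#\\s*", "", m)
    kv <- strsplit(m, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body_idx <- which(!is_meta & nzchar(trimws(lines)))
  if (length(body_idx) < 2) stop("no data rows in ", path)
  df <- tryCatch(
    utils::read.csv(text = paste(lines[body_idx], collapse = "\n"),
                    stringsAsFactors = FALSE),
    error = function(e) stop("malformed CSV in ", path, ": ",
                             conditionMessage(e)))
  attr(df, "meta") <- meta
  attr(df, "line_numbers") <- body_idx[-1]   # file line of each data row
  df
}

check_numeric_col <- function(df, col, path) {
  v <- df[[col]]
  if (is.null(v)) stop(path, ": missing required column '", col, "'")
  if (is.logical(v) && all(is.na(v))) return(as.numeric(v))  # all-NA column
  if (!is.numeric(v)) {
    bad <- attr(df, "line_numbers")[!grepl("^\\s*-?[0-9.eE+-]*\\s*$",
                                           as.character(v))]
    stop(path, ": non-numeric values in column '", col, "' (line ",
         paste(bad, collapse = ", "), ")")
  }
  v
}

#' Read and write survival datasets
#'
#' The survival CSV has columns `experiment_id`, `schedule_label`, `region`,
#' `dose_Gy`, `surviving_fraction`, `sd`, `n_replicates`, with optional
#' `# key=value` metadata lines before the header. Rows with a surviving
#' fraction outside (0, 1] are rejected with their file line numbers.
#'
#' @param path file path.
#' @return `read_survival_csv`: the validated data.frame (metadata in
#'   attribute `"meta"`).
#' @export
read_survival_csv <- function(path) {
  df <- read_csv_with_meta(path)
  req <- c("experiment_id", "schedule_label", "region", "dose_Gy",
           "surviving_fraction", "sd", "n_replicates")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop(path, ": malformed header, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("dose_Gy", "surviving_fraction", "sd", "n_replicates"))
    df[[col]] <- check_numeric_col(df, col, path)
  check_region(df$region)
  sf <- df$surviving_fraction
  bad <- !is.finite(sf) | sf <= 0 | sf > 1
  if (any(bad))
    stop(path, ": surviving fractions outside (0, 1] at line ",
         paste(attr(df, "line_numbers")[bad], collapse = ", "))
  if (any(df$dose_Gy < 0, na.rm = TRUE)) stop(path, ": negative doses")
  out <- df[req]
  attr(out, "meta") <- attr(df, "meta")
  out
}

#' @rdname read_survival_csv
#' @param data data.frame in the survival layout.
#' @param metadata named list written as `# key=value` lines.
#' @return `write_survival_csv`: `path`, invisibly.
#' @export
write_survival_csv <- function(data, path, metadata = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("# %s=%s", k, format(metadata[[k]])), con)
  utils::write.csv(data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write split-dose recovery curves
#'
#' The recovery CSV has columns `tau_h`, `surviving_fraction`, `sd`,
#' `n_replicates`, preceded by `# d1_Gy=` and `# d2_Gy=` metadata lines
#' giving the fraction doses.
#'
#' @param path file path.
#' @return `read_recovery_csv`: a [recovery_curve()] (replicate counts in
#'   attribute `"n_replicates"`).
#' @export
read_recovery_csv <- function(path) {
  df <- read_csv_with_meta(path)
  meta <- attr(df, "meta")
  if (is.null(meta$d1_Gy) || is.null(meta$d2_Gy))
    stop(path, ": missing '# d1_Gy=' / '# d2_Gy=' metadata lines")
  for (col in c("tau_h", "surviving_fraction"))
    check_numeric_col(df, col, path)
  curve <- recovery_curve(df$tau_h, df$surviving_fraction,
                          sd = if ("sd" %in% names(df)) df$sd else NULL,
                          d1 = as.numeric(meta$d1_Gy),
                          d2 = as.numeric(meta$d2_Gy))
  attr(curve, "n_replicates") <-
    if ("n_replicates" %in% names(df)) df$n_replicates else NULL
  curve
}

#' @rdname read_recovery_csv
#' @param curve a [recovery_curve()].
#' @param n_replicates optional replicate counts per point.
#' @return `write_recovery_csv`: `path`, invisibly.
#' @export
write_recovery_csv <- function(curve, path, n_replicates = NULL) {
  stopifnot(inherits(curve, "recovery_curve"))
  if (is.null(n_replicates))
    n_replicates <- attr(curve, "n_replicates") %||% rep(NA, nrow(curve))
  df <- data.frame(tau_h = curve$tau_h,
                   surviving_fraction = curve$surviving_fraction,
                   sd = curve$sd, n_replicates = n_replicates)
  write_survival_like(df, path,
                      list(d1_Gy = attr(curve, "d1"), d2_Gy = attr(curve, "d2")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_survival_like <- function(df, path, metadata) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("# %s=%s", k, format(metadata[[k]])), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write delivery schedules as YAML
#'
#' The schedule file is a YAML mapping with keys `label` and `segments`, the
#' latter a list of `{start_h, duration_h, dose_rate_Gy_per_h}` maps.
#'
#' @param path file path.
#' @return `read_schedule_yaml`: a [delivery_schedule()].
#' @export
read_schedule_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$segments)) stop(path, ": schedule file needs a 'segments' key")
  segs <- do.call(rbind, lapply(y$segments, function(s) {
    data.frame(start_h = as.numeric(s$start_h),
               duration_h = as.numeric(s$duration_h),
               dose_rate_Gy_per_h = as.numeric(s$dose_rate_Gy_per_h))
  }))
  delivery_schedule(segs, label = y$label %||% basename(path))
}

#' @rdname read_schedule_yaml
#' @param schedule a [delivery_schedule()].
#' @return `write_schedule_yaml`: `path`, invisibly.
#' @export
write_schedule_yaml <- function(schedule, path) {
  stopifnot(inherits(schedule, "delivery_schedule"))
  segs <- lapply(seq_len(nrow(schedule$segments)), function(i)
    as.list(schedule$segments[i, ]))
  yaml::write_yaml(list(label = schedule$label, segments = segs), path,
                   precision = 15)
  invisible(path)
}

#' Read an IMK parameter file
#'
#' YAML mapping of cell line to field condition: each cell line has
#' `modulated` and `uniform` blocks (`alpha0`, `beta0`, `a_plus_c`) and an
#' `nte` block (`alpha_b`, `beta_b`, `delta`). A fixture with the shipped
#' literature presets lives at
#' `system.file("extdata", "cell_line_parameters.yaml", package = "imkfit")`.
#'
#' @param path file path.
#' @return Named list per cell line with elements `modulated`, `uniform`
#'   ([te_params()]) and `nte` ([nte_params()]).
#' @export
read_params_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  lapply(y, function(cl) {
    out <- list()
    for (fc in c("modulated", "uniform")) {
      b <- cl[[fc]]
      if (!is.null(b))
        out[[fc]] <- te_params(b$alpha0, b$beta0, b$a_plus_c)
    }
    if (!is.null(cl$nte))
      out$nte <- nte_params(cl$nte$alpha_b, cl$nte$beta_b, cl$nte$delta)
    out
  })
}
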