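#' Write an actigraphy record to CSV
#'
#' Dialect: header `animal_id,t_s,activity,temp_c`, one row per bin, `t_s` =
#' integer seconds since recording start at bin start. Temperature is
#' written with 6 significant digits; a missing temperature is an empty
#' cell, never 0. Output bytes are deterministic for a fixed record.
#'
#' @param record An [actigraphy_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "actigraphy_record"))
  t_s <- bin_times(record)
  lines <- c("animal_id,t_s,activity,temp_c",
             sprintf("%s,%d,%d,%s", record$animal_id, as.integer(t_s),
                     record$activity, fmt_num(record$temperature)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read an actigraphy record from CSV
#'
#' Validates the dialect written by [write_record()]: exact header, integer
#' non-negative activity, a strictly uniform time grid (a dropped or
#' duplicated bin is a format error — the analysis assumes a complete
#' activity series). Empty temperature cells become `NA`. Errors name the
#' offending data row (1 = first row after the header).
#'
#' @param path CSV file path.
#' @param schedule [light_schedule()] to attach (the record file itself is
#'   schedule-free; the cohort manifest carries the schedule).
#' @param group Group label to attach.
#' @param bin_seconds Bin width override, only needed for a 1-row file where
#'   the grid spacing cannot be inferred (default 300 then).
#' @return An [actigraphy_record()].
#' @export
read_record <- function(path, schedule = light_schedule("LD"), group = "unknown",
                        bin_seconds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "animal_id,t_s,activity,temp_c")
    stop("unknown header in ", path,
         " (expected 'animal_id,t_s,activity,temp_c')", call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(body, ",", fixed = TRUE)
  bad_ncol <- which(!vapply(parts, length, 0L) %in% c(3L, 4L))
  if (length(bad_ncol))
    stop(sprintf("malformed row %d in %s", bad_ncol[1], path), call. = FALSE)
  get_col <- function(k) vapply(parts, function(p) if (length(p) >= k) p[k] else "", "")
  ids <- get_col(1)
  t_raw <- get_col(2); a_raw <- get_col(3); tc_raw <- get_col(4)
  bad_t <- which(!grepl("^[0-9]+$", t_raw))
  if (length(bad_t))
    stop(sprintf("non-integer time at row %d in %s", bad_t[1], path), call. = FALSE)
  bad_a <- which(!grepl("^[0-9]+$", a_raw))
  if (length(bad_a))
    stop(sprintf("invalid activity at row %d in %s (must be a non-negative integer)",
                 bad_a[1], path), call. = FALSE)
  t_s <- as.numeric(t_raw)
  if (length(t_s) > 1) {
    dt <- diff(t_s)
    if (length(unique(dt)) != 1 || dt[1] <= 0)
      stop(sprintf("non-uniform time grid at row %d in %s (gap or duplicate bin)",
                   which(dt != dt[1])[1] + 1, path), call. = FALSE)
    bin_seconds <- dt[1]
  } else if (is.null(bin_seconds)) bin_seconds <- 300L
  temp <- suppressWarnings(as.numeric(tc_raw))
  bad_temp <- which(is.na(temp) & nzchar(tc_raw))
  if (length(bad_temp))
    stop(sprintf("invalid temperature at row %d in %s", bad_temp[1], path),
         call. = FALSE)
  if (length(unique(ids)) != 1)
    stop("multiple animal_id values in one record file: ", path, call. = FALSE)
  actigraphy_record(ids[1], group, as.integer(a_raw), temp,
                    bin_seconds = as.integer(bin_seconds), schedule = schedule,
                    t0_s = t_s[1])
}

#' Write a cohort (records + manifest) to a directory
#'
#' One CSV per animal plus `manifest.csv` with columns `animal_id`, `group`,
#' `file`, `cycle`, `lights_off_zt`, `anchor_zt_at_start`, `dd_start_s`
#' (empty for pure LD).
#'
#' @param records List of [actigraphy_record()]s.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- character(0)
  for (rec in records) {
    fname <- paste0(rec$animal_id, ".csv")
    write_record(rec, file.path(dir, fname))
    sch <- rec$schedule
    rows <- c(rows, sprintf("%s,%s,%s,%s,%s,%s,%s",
                            rec$animal_id, rec$group, fname, sch$cycle,
                            fmt_num(sch$lights_off_zt), fmt_num(sch$anchor_zt),
                            if (is.na(sch$dd_start_s)) "" else fmt_num(sch$dd_start_s)))
  }
  mpath <- file.path(dir, "manifest.csv")
  con <- file(mpath, open = "wb")
  on.exit(close(con))
  writeLines(c("animal_id,group,file,cycle,lights_off_zt,anchor_zt_at_start,dd_start_s",
               rows), con, sep = "\n")
  invisible(mpath)
}

#' Read a cohort manifest
#'
#' Validates: unique `animal_id`, non-empty group labels, every referenced
#' file exists (paths resolved relative to the manifest's directory).
#'
#' @param path Manifest CSV path.
#' @return data.frame with the manifest columns plus `path` (resolved file
#'   path per record).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(animal_id = "character", group = "character",
                                      file = "character", cycle = "character"))
  need <- c("animal_id", "group", "file", "cycle", "lights_off_zt",
            "anchor_zt_at_start", "dd_start_s")
  if (!all(need %in% names(m)))
    stop("manifest missing columns: ",
         paste(setdiff(need, names(m)), collapse = ", "), call. = FALSE)
  dup <- which(duplicated(m$animal_id))
  if (length(dup))
    stop(sprintf("duplicate animal_id at manifest row %d", dup[1]), call. = FALSE)
  blank <- which(!nzchar(m$group))
  if (length(blank))
    stop(sprintf("empty group label at manifest row %d", blank[1]), call. = FALSE)
  bad_cycle <- which(!m$cycle %in% c("LD", "DD"))
  if (length(bad_cycle))
    stop(sprintf("unknown cycle at manifest row %d", bad_cycle[1]), call. = FALSE)
  m$path <- file.path(dirname(path), m$file)
  missing <- which(!file.exists(m$path))
  if (length(missing))
    stop(sprintf("referenced file missing at manifest row %d: %s",
                 missing[1], m$file[missing[1]]), call. = FALSE)
  m
}

#' Load every record referenced by a manifest
#'
#' @param path Manifest CSV path.
#' @return Named list of [actigraphy_record()]s with schedules attached.
#' @export
load_cohort <- function(path) {
  m <- read_manifest(path)
  records <- list()
  for (i in seq_len(nrow(m))) {
    sch <- light_schedule(m$cycle[i], lights_off_zt = m$lights_off_zt[i],
                          anchor_zt = m$anchor_zt_at_start[i],
                          dd_start_s = if (is.na(m$dd_start_s[i])) NA_real_
                                       else m$dd_start_s[i])
    records[[m$animal_id[i]]] <- read_record(m$path[i], schedule = sch,
                                             group = m$group[i])
  }
  records
}

#' Write a result table as CSV
#'
#' Byte-deterministic writer for the pipeline's result tables (markers,
#' periods, profiles, per-bin tests): floating point with 6 significant
#' digits, `NA` as empty cells, one header row.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) fmt_num(col)
    else { s <- as.character(col); s[is.na(s)] <- ""; s }
  })
  body <- if (nrow(df)) do.call(paste, c(cols, sep = ",")) else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = ","), body), con, sep = "\n")
  invisible(path)
}

#' Write a JSON results report
#'
#' Keys are sorted recursively for stable output; scalars are unboxed.
#'
#' @param results Named list (arbitrarily nested).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(results, path) {
  sort_keys <- function(x) {
    if (is.list(x) && !is.null(names(x)) && length(x))
      lapply(x[order(names(x))], sort_keys)
    else x
  }
  jsonlite::write_json(sort_keys(results), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
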