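## Minimal TOML subset for study configs: [section] / [a.b] tables,
## key = value with strings, numbers, booleans and flat arrays. This covers
## the fixture/CLI configuration schema; it is not a general TOML parser.

toml_scalar <- function(v) {
  if (is.character(v)) paste0("\"", v, "\"")
  else if (is.logical(v)) ifelse(v, "true", "false")
  else format(v, digits = 15, scientific = FALSE, trim = TRUE)
}

#' Write a nested list as a TOML config
#'
#' @param cfg Named list of named lists (sections of key/value pairs;
#'   values: scalars or flat vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  lines <- character(0)
  for (sec in names(cfg)) {
    lines <- c(lines, paste0("[", sec, "]"))
    for (key in names(cfg[[sec]])) {
      v <- cfg[[sec]][[key]]
      rhs <- if (length(v) == 1L) toml_scalar(v)
             else paste0("[", paste(vapply(v, toml_scalar, ""),
                                    collapse = ", "), "]")
      lines <- c(lines, paste0(key, " = ", rhs))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

parse_toml_value <- function(s) {
  s <- trimws(s)
  if (grepl("^\\[", s)) {
    inner <- sub("^\\[", "", sub("\\]$", "", s))
    if (trimws(inner) == "") return(list())
    parts <- strsplit(inner, ",")[[1L]]
    vals <- lapply(parts, parse_toml_value)
    return(unlist(vals))
  }
  if (grepl("^\"", s)) return(gsub("^\"|\"$", "", s))
  if (s %in% c("true", "false")) return(s == "true")
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  stop2("cannot parse TOML value: ", s)
}

#' Read a TOML config written by [write_config()]
#'
#' @param path Path to the file.
#' @return Nested named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop2("no such config file: ", path)
  lines <- readLines(path, warn = FALSE)
  cfg <- list()
  sec <- NULL
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      cfg[[sec]] <- cfg[[sec]] %||% list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1L, eq - 1L))
      val <- parse_toml_value(substr(ln, eq + 1L, nchar(ln)))
      if (is.null(sec)) cfg[[key]] <- val else cfg[[sec]][[key]] <- val
    } else stop2("cannot parse config line: ", ln)
  }
  cfg
}

## rebuild layout / schedule objects from a fixture config
layout_from_config <- function(cfg) {
  default_tank_layout(n_tanks = as.integer(cfg$layout$n_tanks),
                      fish_per_tank = as.integer(cfg$layout$fish_per_tank),
                      px_per_cm = cfg$layout$px_per_cm,
                      tank_cm = cfg$layout$tank_cm)
}

schedule_from_config <- function(cfg) {
  light_schedule(cfg$schedule$lights_on_hour, cfg$schedule$lights_off_hour,
                 cfg$schedule$recording_interval,
                 cfg$schedule$recording_duration)
}
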