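# Flat-file interfaces: traces and dwell sets as TSV with '#'-prefixed
# metadata headers, rate/config files as flat YAML, structured results as
# JSON.

meta_header_lines <- function(meta) {
  flat <- unlist(meta)
  if (!length(flat)) return(character(0))
  paste0("# ", names(flat), " = ", as.character(flat))
}

parse_meta_header <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- list()
  for (p in kv) {
    if (length(p) != 2) next
    v <- suppressWarnings(as.numeric(p[2]))
    out[[p[1]]] <- if (is.na(v)) p[2] else v
  }
  out
}

#' Write an extension trace as TSV
#'
#' Two tab-separated columns `time_s`, `extension_nm` preceded by
#' '#'-prefixed `key = value` metadata lines (sampling rate, decimation,
#' condition labels, seed).
#'
#' @param trace An `extension_trace`.
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "extension_trace"))
  m <- trace$meta
  meta <- c(list(f_s = m$f_s, decimate = m$decimate, duration = m$duration,
                 noise_sd = m$noise_sd, z_CS = m$z_CS,
                 jump_pos = m$jump_pos, jump_neg = m$jump_neg,
                 supercoiling_sign = m$supercoiling_sign,
                 drift_rate = m$drift_rate),
            if (!is.null(m$seed)) list(seed = m$seed),
            m$label,
            lapply(unclass(m$rates), identity))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header_lines(meta), con)
  writeLines("time_s\textension_nm", con)
  utils::write.table(data.frame(time_s = trace$t, extension_nm = trace$z),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an extension trace written by [write_trace()]
#'
#' @param path Input path.
#' @return List with `t`, `z` and `meta` (parsed header key-values).
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- parse_meta_header(lines[is_meta])
  body <- lines[!is_meta]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  structure(list(t = df$time_s, z = df$extension_nm, meta = meta),
            class = "extension_trace")
}

#' Write a dwell set as TSV
#'
#' Columns `label`, (optional) `start_s`, `duration_s`, `censored`, with
#' the applied `t_min` in the metadata header.
#'
#' @param dwells A `dwell_set`.
#' @param path Output path.
#' @export
write_dwells <- function(dwells, path) {
  stopifnot(inherits(dwells, "dwell_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header_lines(list(t_min = attr(dwells, "t_min"))), con)
  df <- as.data.frame(dwells)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dwell set written by [write_dwells()]
#'
#' @param path Input path.
#' @return A `dwell_set` data frame.
#' @export
read_dwells <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- parse_meta_header(lines[is_meta])
  df <- utils::read.table(text = lines[!is_meta], header = TRUE, sep = "\t")
  df$censored <- as.logical(df$censored)
  as_dwell_set(df, t_min = if (is.null(meta$t_min)) 0 else meta$t_min)
}

#' Write rate constants (optionally with a model id) to a flat config
#'
#' Flat YAML key-value file; rates in 1/s (`k1` in 1/nM/s, `R_conc` in
#' nM).
#'
#' @param rates A [rate_constants()] object.
#' @param path Output path.
#' @param model_id Optional dwell-model identifier stored alongside.
#' @export
write_rates_config <- function(rates, path, model_id = NULL) {
  r <- unclass(as_rate_constants(rates))
  if (!is.null(model_id)) r <- c(list(model_id = model_id), r)
  yaml::write_yaml(r, path)
  invisible(path)
}

#' Read rate constants from a flat config file
#'
#' @param path Input path (YAML key-value as written by
#'   [write_rates_config()]).
#' @return List with `rates` ([rate_constants()]) and `model_id` (or
#'   `NULL`).
#' @export
read_rates_config <- function(path) {
  y <- yaml::read_yaml(path)
  model_id <- y$model_id
  y$model_id <- NULL
  list(rates = do.call(rate_constants, y), model_id = model_id)
}

#' Read a full pipeline run configuration
#'
#' Flat YAML with per-stage keys; see [run_pipeline()] for the recognized
#' fields.
#'
#' @param path Input path.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

write_json_result <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
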