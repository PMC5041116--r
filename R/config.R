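#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments are
#' ignored. Keys are exactly the [life_history()] parameter names, plus an
#' optional `s` (selfing rate). Unknown keys and out-of-range values are
#' rejected with distinct messages.
#'
#' @param path Path to the configuration file.
#' @return List with `params` (a [life_history()]) and `s` (numeric or
#'   `NULL`).
#' @seealso [write_config()]
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line(s): ",
         paste(shQuote(lines[bad]), collapse = ", "), call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  if (anyNA(vals))
    stop("non-numeric config value(s) for: ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  if (anyDuplicated(keys))
    stop("duplicated config key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  allowed <- c(names(formals(life_history)), "s")
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vals <- as.list(vals); names(vals) <- keys
  s <- vals[["s"]]
  vals[["s"]] <- NULL
  list(params = do.call(life_history, vals), s = s)
}

#' Write a flat key-value configuration file
#'
#' Inverse of [read_config()]: round-trips a parameter set exactly (values
#' written with full precision).
#'
#' @param params A [life_history()] object.
#' @param path Output path.
#' @param s Optional selfing rate to record.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, s = NULL) {
  p <- unclass(as_life_history(params))
  if (!is.null(s)) p$s <- s
  lines <- sprintf("%s = %s", names(p),
                   vapply(p, function(v) format(v, digits = 17), ""))
  writeLines(lines, path)
  invisible(path)
}
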