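# Reading, validating and writing patient panel tables.
#
# A panel table holds one row per patient: an opaque id, age in years, total
# IgE (tIgE, kU/L, may be missing) and specific IgE (sIgE, kU/L) to each of
# the 11 catalog components. The on-disk format is delimited text with header
# `id,age,tIgE,Der f 1,...,Der p 23`.

new_hdm_panel <- function(df) {
  comps <- hdm_components()
  df <- df[, c("id", "age", "tIgE", comps), drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("hdm_panel", "data.frame"))
}

validate_hdm_panel <- function(df) {
  comps <- hdm_components()
  need <- c("id", "age", "tIgE", comps)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate patient id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (nrow(df)) {
    if (any(is.na(df$age))) {
      stop("non-numeric or missing age in row id(s): ",
           paste(df$id[is.na(df$age)], collapse = ", "))
    }
    if (any(df$age < 0 | df$age >= 150)) {
      stop("age out of range [0, 150) in row id(s): ",
           paste(df$id[df$age < 0 | df$age >= 150], collapse = ", "))
    }
    for (k in comps) {
      v <- df[[k]]
      if (any(is.na(v))) {
        stop("missing or non-numeric sIgE for '", k, "' in row id(s): ",
             paste(df$id[is.na(v)], collapse = ", "))
      }
      if (any(v < 0)) {
        stop("negative sIgE for '", k, "' in row id(s): ",
             paste(df$id[v < 0], collapse = ", "))
      }
    }
    bad_tige <- !is.na(df$tIgE) & df$tIgE < 0
    if (any(bad_tige)) {
      stop("negative tIgE in row id(s): ", paste(df$id[bad_tige], collapse = ", "))
    }
  }
  df
}

#' Construct a panel table from a data frame
#'
#' Validates a data frame of patient panel results (id, age, tIgE plus one
#' sIgE column per catalog component, kU/L) and returns an `hdm_panel`.
#' Missing tIgE is tolerated (it is descriptive only); a missing sIgE value is
#' an error, because the multiplex assay always reports the complete panel and
#' an absent value signals a corrupt export.
#'
#' @param df data frame with columns `id`, `age`, `tIgE` and the 11 components
#'   of [hdm_components()].
#' @return an `hdm_panel` (a validated data frame in canonical column order).
#' @export
hdm_panel <- function(df) {
  df <- as.data.frame(df, check.names = FALSE, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  for (k in c("age", "tIgE", hdm_components())) {
    if (!is.null(df[[k]])) df[[k]] <- as.numeric(df[[k]])
  }
  new_hdm_panel(validate_hdm_panel(df))
}

#' Read a patient panel table
#'
#' Reads a delimited panel file and returns a validated [hdm_panel()]. Header
#' matching is case- and whitespace-insensitive (`Der_f_1` matches `Der f 1`);
#' unknown extra columns are dropped with a warning. Any row with a
#' non-parseable or missing sIgE value, a negative concentration, an age
#' outside `[0, 150)` or a duplicated id aborts the read with the offending
#' column or row id named — rows are never silently coerced.
#'
#' @param path path to a CSV/TSV panel file.
#' @param delim field delimiter (default `","`).
#' @return an `hdm_panel`.
#' @export
read_panel <- function(path, delim = ",") {
  if (!file.exists(path)) {
    stop("panel file not found: ", path)
  }
  raw <- read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "", na.strings = NULL,
                    fileEncoding = "UTF-8")
  want <- c("id", "age", "tIgE", hdm_components())
  pos <- match(normalize_header(want), normalize_header(names(raw)))
  if (anyNA(pos)) {
    stop("missing required column(s): ", paste(want[is.na(pos)], collapse = ", "))
  }
  extra <- setdiff(seq_along(raw), pos)
  if (length(extra)) {
    warning("ignoring unrecognised column(s): ",
            paste(names(raw)[extra], collapse = ", "))
  }
  df <- raw[pos]
  names(df) <- want

  parse_num <- function(v, allow_missing) {
    v <- trimws(v)
    miss <- v %in% c("", "NA")
    num <- suppressWarnings(as.numeric(v))
    garbled <- is.na(num) & !miss
    if (any(garbled)) {
      return(list(x = replace(num, garbled, NA_real_), ok = FALSE))
    }
    if (!allow_missing && any(miss)) {
      return(list(x = num, ok = FALSE))
    }
    list(x = num, ok = TRUE)
  }
  df$id <- trimws(df$id)
  for (k in c("age", hdm_components())) {
    df[[k]] <- parse_num(df[[k]], allow_missing = FALSE)$x
  }
  tg <- parse_num(df$tIgE, allow_missing = TRUE)
  if (!tg$ok) {
    stop("non-numeric tIgE in row id(s): ",
         paste(df$id[is.na(tg$x) & !trimws(raw[[pos[3]]]) %in% c("", "NA")],
               collapse = ", "))
  }
  df$tIgE <- tg$x
  new_hdm_panel(validate_hdm_panel(df))
}

#' Write a panel table
#'
#' Serializes an [hdm_panel()] in canonical column order. Concentrations and
#' ages are written with at most 4 decimal places (trailing zeros trimmed);
#' missing tIgE becomes an empty field. `write_panel(read_panel(f), g)` is the
#' canonical form of `f` and round-trips losslessly at that precision.
#'
#' @param table an `hdm_panel`.
#' @param path output file path.
#' @param delim field delimiter (default `","`).
#' @return the path, invisibly.
#' @export
write_panel <- function(table, path, delim = ",") {
  if (!inherits(table, "hdm_panel")) {
    stop("'table' must be an hdm_panel")
  }
  comps <- hdm_components()
  lines <- paste(c("id", "age", "tIgE", comps), collapse = delim)
  if (nrow(table)) {
    cols <- c(list(table$id, fmt_conc(table$age), fmt_conc(table$tIgE)),
              lapply(comps, function(k) fmt_conc(table[[k]])))
    lines <- c(lines, do.call(paste, c(cols, sep = delim)))
  }
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @export
print.hdm_panel <- function(x, ...) {
  cat("<hdm_panel> ", nrow(x), " patient(s), ",
      length(hdm_components()), " components\n", sep = "")
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x), 5), ...)
    if (nrow(x) > 5) cat("... (", nrow(x) - 5, " more rows)\n", sep = "")
  }
  invisible(x)
}
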