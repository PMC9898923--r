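# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounding convention used for every reported percentage and ratio: halves
#' are rounded away from zero (so 27.505 -> 27.51), unlike [base::round()],
#' which rounds halves to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_out(2.345, 2) # 2.35
round_half_out <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Serialize a concentration (or age) with at most 4 decimal places and no
# trailing zeros; NA becomes the empty field.
fmt_conc <- function(x) {
  out <- sprintf("%.4f", round(as.numeric(x), 4))
  out <- sub("0+$", "", out)
  out <- sub("\\.$", "", out)
  out[is.na(x)] <- ""
  out
}

# x * log(y) with the 0 * log(0) == 0 convention.
xlogy <- function(x, y) {
  out <- numeric(length(x))
  nz <- x != 0
  out[nz] <- x[nz] * log(y[nz])
  out
}

# All 2^m binary assignments as a matrix; column i varies with period 2^(i-1),
# so row index == 1 + sum(bits * 2^(i-1)).
bitgrid <- function(m) {
  if (m == 0L) {
    return(matrix(0L, nrow = 1L, ncol = 0L))
  }
  g <- as.matrix(do.call(expand.grid, rep(list(0:1), m)))
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

# Evaluate fun() under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL uses (and advances) the current stream.
run_seeded <- function(seed, fun) {
  if (is.null(seed)) {
    return(fun())
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fun()
}

# Keep the order `ref` imposes on the subset `x`.
sort_canonical <- function(x, ref) {
  x[order(match(x, ref))]
}

# Parse "Der f 1=1,Der p 2=0" into a named integer vector.
parse_assignment <- function(spec) {
  if (is.numeric(spec)) {
    return(check_assignment(spec))
  }
  spec <- trimws(spec)
  if (!nzchar(spec)) {
    return(setNames(integer(0), character(0)))
  }
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) {
    stop("malformed assignment term(s): ", paste(parts[bad], collapse = "; "))
  }
  vals <- vapply(kv, function(p) trimws(p[2]), "")
  nms <- vapply(kv, function(p) trimws(p[1]), "")
  check_assignment(setNames(as.integer(vals), nms))
}

check_assignment <- function(a) {
  if (length(a) && (is.null(names(a)) || any(!nzchar(names(a))))) {
    stop("assignments must be named")
  }
  if (anyDuplicated(names(a))) {
    stop("duplicated variable in assignment: ",
         paste(unique(names(a)[duplicated(names(a))]), collapse = ", "))
  }
  vals <- as.integer(a)
  if (any(!vals %in% c(0L, 1L))) {
    stop("assignment values must be 0 or 1")
  }
  setNames(vals, names(a))
}
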