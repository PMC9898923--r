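# Threshold binarization and descriptive cohort statistics.

new_sens_matrix <- function(x, ids, ages = NULL) {
  storage.mode(x) <- "integer"
  if (is.null(colnames(x))) {
    stop("sensitization matrix needs component column names")
  }
  if (any(!x %in% c(0L, 1L))) {
    stop("sensitization entries must be 0 or 1")
  }
  rownames(x) <- NULL
  structure(list(x = x, ids = as.character(ids),
                 ages = if (is.null(ages)) NULL else as.numeric(ages),
                 components = colnames(x)),
            class = "sens_matrix")
}

#' @export
print.sens_matrix <- function(x, ...) {
  cat("<sens_matrix> ", nrow(x$x), " patient(s) x ", ncol(x$x),
      " component(s); ", sum(rowSums(x$x) > 0), " with >=1 positive\n", sep = "")
  invisible(x)
}

# Accept a sens_matrix or a plain binary matrix with column names.
as_binary_matrix <- function(data) {
  if (inherits(data, "sens_matrix")) {
    return(data$x)
  }
  x <- as.matrix(data)
  storage.mode(x) <- "integer"
  if (is.null(colnames(x))) stop("binary data matrix needs column names")
  if (any(!x %in% c(0L, 1L))) stop("data entries must be 0 or 1")
  x
}

#' Binarize a panel at the sensitization threshold
#'
#' Converts sIgE concentrations to presence/absence of sensitization. An entry
#' is 1 exactly when sIgE >= `threshold`; the assay's reference threshold of
#' 0.31 kU/L is the default, and the boundary is inclusive (a measurement of
#' exactly 0.31 kU/L counts as sensitized; only strictly lower values are
#' discarded as negative).
#'
#' @param table an [hdm_panel()].
#' @param threshold sensitization threshold in kU/L (> 0, default 0.31).
#' @return a `sens_matrix`: binary patient x component matrix with patient ids
#'   and ages carried through.
#' @export
binarize <- function(table, threshold = 0.31) {
  if (!inherits(table, "hdm_panel")) stop("'table' must be an hdm_panel")
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("'threshold' must be a single positive number")
  }
  comps <- hdm_components()
  x <- as.matrix(as.data.frame(table)[comps])
  new_sens_matrix((x >= threshold) * 1L, ids = table$id, ages = table$age)
}

#' Keep only sensitized patients
#'
#' Retains exactly the rows with at least one positive component, preserving
#' order. The result may be empty.
#'
#' @param m a `sens_matrix`.
#' @return a `sens_matrix` of the sensitized subset.
#' @export
filter_sensitized <- function(m) {
  if (!inherits(m, "sens_matrix")) stop("'m' must be a sens_matrix")
  keep <- rowSums(m$x) > 0
  new_sens_matrix(m$x[keep, , drop = FALSE], ids = m$ids[keep],
                  ages = if (is.null(m$ages)) NULL else m$ages[keep])
}

#' Percentage share
#'
#' `100 * count / denom`, rounded half-away-from-zero to 2 decimals — the
#' convention under which every printed share in the cohort summary is exactly
#' reproducible from its integer numerator and denominator.
#'
#' @param count non-negative integer, `count <= denom`.
#' @param denom positive integer denominator.
#' @return percentage rounded to 2 decimals.
#' @export
#' @examples
#' share(2821, 5170) # 54.56
share <- function(count, denom) {
  if (any(denom == 0)) stop("share(): zero denominator")
  if (any(count < 0 | count > denom)) stop("share(): need 0 <= count <= denom")
  round_half_out(100 * count / denom, 2)
}

#' Summarize a sensitized cohort
#'
#' Per-component counts, shares and sIgE summaries in the layout of a cohort
#' characteristics table: one block for the whole sensitized sample, one for
#' children (age < `child_cutoff`) and one for adults (age >= `child_cutoff`).
#' By default the share denominator is the whole sensitized sample for every
#' stratum (so children + adult shares of one component sum to its overall
#' share); set `stratum_denominator = TRUE` to use each stratum's own size
#' instead. Mean and SD of sIgE are computed among the positive patients of
#' the stratum only; an SD over fewer than two values is reported as `NA`.
#'
#' @param table the [hdm_panel()] the matrix was derived from (source of the
#'   sIgE magnitudes and tIgE).
#' @param m `filter_sensitized(binarize(table, threshold))`.
#' @param child_cutoff age separating children from adults (default 18).
#' @param stratum_denominator use stratum sizes as share denominators.
#' @return a `cohort_summary`: list with `components` (one row per component)
#'   and `totals` (sample sizes, child:adult ratio, mean ages, mean tIgE).
#' @export
cohort_summary <- function(table, m, child_cutoff = 18,
                           stratum_denominator = FALSE) {
  if (!inherits(table, "hdm_panel")) stop("'table' must be an hdm_panel")
  if (!inherits(m, "sens_matrix")) stop("'m' must be a sens_matrix")
  comps <- m$components
  idx <- match(m$ids, table$id)
  if (anyNA(idx)) stop("matrix ids not found in panel table")
  sige <- as.matrix(as.data.frame(table)[comps])[idx, , drop = FALSE]
  thr_pos <- m$x == 1L

  n_sens <- nrow(m$x)
  is_child <- m$ages < child_cutoff
  n_child <- sum(is_child)
  n_adult <- n_sens - n_child

  stratum_stats <- function(rows, denom) {
    pos <- thr_pos[rows, , drop = FALSE]
    vals <- sige[rows, , drop = FALSE]
    n_pos <- colSums(pos)
    mean_s <- sd_s <- rep(NA_real_, length(comps))
    for (j in seq_along(comps)) {
      v <- vals[pos[, j], j]
      if (length(v) >= 1) mean_s[j] <- mean(v)
      if (length(v) >= 2) sd_s[j] <- sd(v)
    }
    list(n = n_pos,
         share = if (denom > 0) share(n_pos, denom) else rep(NA_real_, length(comps)),
         mean = mean_s, sd = sd_s)
  }

  all_rows <- rep(TRUE, n_sens)
  st_all <- stratum_stats(all_rows, n_sens)
  dc <- if (stratum_denominator) n_child else n_sens
  da <- if (stratum_denominator) n_adult else n_sens
  st_child <- stratum_stats(is_child, dc)
  st_adult <- stratum_stats(!is_child, da)

  components <- data.frame(
    component = comps,
    n_all = st_all$n, share_all = st_all$share,
    mean_sige_all = st_all$mean, sd_sige_all = st_all$sd,
    n_children = st_child$n, share_children = st_child$share,
    mean_sige_children = st_child$mean, sd_sige_children = st_child$sd,
    n_adults = st_adult$n, share_adults = st_adult$share,
    mean_sige_adults = st_adult$mean, sd_sige_adults = st_adult$sd,
    stringsAsFactors = FALSE
  )

  tige <- table$tIgE[idx]
  mean_or_na <- function(v) if (length(v) && any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_
  totals <- list(
    n_total_tested = nrow(table),
    n_sensitized = n_sens,
    pct_sensitized = if (nrow(table) > 0) share(n_sens, nrow(table)) else NA_real_,
    n_children = n_child,
    n_adults = n_adult,
    share_children = if (n_sens > 0) share(n_child, n_sens) else NA_real_,
    share_adults = if (n_sens > 0) share(n_adult, n_sens) else NA_real_,
    child_adult_ratio = if (n_adult > 0) round_half_out(n_child / n_adult, 2) else NA_real_,
    child_cutoff = child_cutoff,
    mean_age = mean_or_na(m$ages),
    mean_age_children = mean_or_na(m$ages[is_child]),
    mean_age_adults = mean_or_na(m$ages[!is_child]),
    mean_tige = mean_or_na(tige),
    mean_tige_children = mean_or_na(tige[is_child]),
    mean_tige_adults = mean_or_na(tige[!is_child])
  )
  structure(list(components = components, totals = totals,
                 stratum_denominator = stratum_denominator),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  t <- x$totals
  cat("<cohort_summary> ", t$n_sensitized, " sensitized of ", t$n_total_tested,
      " tested (", t$pct_sensitized, "%)\n", sep = "")
  cat("  children: ", t$n_children, " (", t$share_children, "%), adults: ",
      t$n_adults, " (", t$share_adults, "%), ratio ", t$child_adult_ratio,
      "\n", sep = "")
  print(x$components[, c("component", "n_all", "share_all",
                         "n_children", "n_adults")], row.names = FALSE)
  invisible(x)
}

#' Age bands
#'
#' Half-open age bands partitioning `[0, Inf)`. The default cutpoints
#' (1, 3, 6, 12, 18, 25, 36, 44, 60 years) follow the conventional pediatric
#' strata — infancy up to 1, toddler 1-3, preschool 3-6, primary school 6-12,
#' puberty 12-18 — and adult strata bounded by the beginning and end of youth
#' (25, 44), an intermediate point at 36, and the end of middle age (60).
#'
#' @param cutpoints strictly increasing positive ages in years.
#' @return an `age_bands` object with breaks and interval labels.
#' @export
age_bands <- function(cutpoints = c(1, 3, 6, 12, 18, 25, 36, 44, 60)) {
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) < 1 || any(cutpoints <= 0) ||
      any(diff(cutpoints) <= 0)) {
    stop("'cutpoints' must be strictly increasing and positive")
  }
  breaks <- c(0, cutpoints, Inf)
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  labels <- ifelse(is.finite(hi),
                   sprintf("[%s,%s)", fmt_conc(lo), fmt_conc(hi)),
                   sprintf("%s+", fmt_conc(lo)))
  structure(list(cutpoints = cutpoints, breaks = breaks, labels = labels),
            class = "age_bands")
}

#' Assign ages to bands
#'
#' Maps each age to the unique half-open band `[lower, upper)` containing it,
#' so a boundary age belongs to the band it opens (age 3 falls in `[3,6)`).
#'
#' @param ages numeric vector of ages in years (non-negative).
#' @param bands an [age_bands()] object.
#' @return factor of band labels, one per age, with all band levels.
#' @export
age_stratify <- function(ages, bands = age_bands()) {
  if (!inherits(bands, "age_bands")) stop("'bands' must be an age_bands object")
  ages <- as.numeric(ages)
  if (any(is.na(ages)) || any(ages < 0)) stop("ages must be non-negative")
  i <- findInterval(ages, bands$breaks)
  factor(bands$labels[i], levels = bands$labels)
}

#' Age-stratified sensitization frequencies
#'
#' For every age band and component, the percentage of the band's patients
#' positive to the component (`freq_within_band`), plus the same counts as a
#' percentage of the whole sample (`freq_of_total`) since published age
#' profiles do not always state which denominator they use. Frequencies for an
#' empty band are `NA`, never 0.
#'
#' @param m a non-empty `sens_matrix` with ages.
#' @param bands an [age_bands()] object.
#' @return an `age_profile`: list of two band x component percent matrices and
#'   the band sizes.
#' @export
group_frequency_table <- function(m, bands = age_bands()) {
  if (!inherits(m, "sens_matrix")) stop("'m' must be a sens_matrix")
  if (nrow(m$x) == 0) stop("empty sensitization matrix")
  if (is.null(m$ages)) stop("matrix carries no ages")
  band <- age_stratify(m$ages, bands)
  sizes <- as.integer(table(band))
  names(sizes) <- bands$labels
  counts <- matrix(0L, length(bands$labels), ncol(m$x),
                   dimnames = list(bands$labels, m$components))
  agg <- rowsum(m$x, band)
  counts[rownames(agg), ] <- agg
  freq_within <- counts / sizes * 100
  freq_within[sizes == 0, ] <- NA_real_
  freq_total <- counts / nrow(m$x) * 100
  structure(list(freq_within_band = freq_within, freq_of_total = freq_total,
                 counts = counts, band_sizes = sizes),
            class = "age_profile")
}

#' @export
print.age_profile <- function(x, ...) {
  cat("<age_profile> ", nrow(x$counts), " band(s) x ", ncol(x$counts),
      " component(s)\n", sep = "")
  print(round(x$freq_within_band, 2))
  invisible(x)
}
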