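# End-to-end orchestration: read/simulate -> binarize -> summarize -> learn
# -> query -> report, with deterministic artifacts.

#' Default conditional-probability queries
#'
#' The co-sensitization query patterns reported for the 11-component HDM
#' panel — each node's probability given presence or absence of its
#' neighbourhood (e.g. Der f 1 given Der f 2, Der p 1 and Der p 23 all
#' present; Der f 2 given Der p 11 absent) — so pipeline reports have the
#' familiar shape out of the box.
#'
#' @return data frame with columns `name`, `target`, `evidence` (assignment
#'   strings understood by [query()]).
#' @export
default_cpd_queries <- function() {
  q <- rbind(
    c("derp23_given_p1_p5_p7_present", "Der p 23=1",
      "Der p 1=1,Der p 5=1,Der p 7=1"),
    c("derp23_absent_given_p1_p5_p7_absent", "Der p 23=0",
      "Der p 1=0,Der p 5=0,Der p 7=0"),
    c("derf1_given_f2_p1_p23_present", "Der f 1=1",
      "Der f 2=1,Der p 1=1,Der p 23=1"),
    c("derp10_given_f1_f2_p20_p23_present", "Der p 10=1",
      "Der f 1=1,Der f 2=1,Der p 20=1,Der p 23=1"),
    c("derp10_absent_given_f1_f2_p20_p23_present", "Der p 10=0",
      "Der f 1=1,Der f 2=1,Der p 20=1,Der p 23=1"),
    c("derp10_absent_given_f1_f2_p20_p23_absent", "Der p 10=0",
      "Der f 1=0,Der f 2=0,Der p 20=0,Der p 23=0"),
    c("derf2_given_p1_p21_p23_p7_present", "Der f 2=1",
      "Der p 1=1,Der p 21=1,Der p 23=1,Der p 7=1"),
    c("derf2_given_p1_p21_p23_p7_absent", "Der f 2=1",
      "Der p 1=0,Der p 21=0,Der p 23=0,Der p 7=0"),
    c("derp2_given_f2_p1_present", "Der p 2=1", "Der f 2=1,Der p 1=1"),
    c("derp11_given_f2_present", "Der p 11=1", "Der f 2=1"),
    c("derf2_given_p11_absent", "Der f 2=1", "Der p 11=0"),
    c("derp20_given_f2_p1_p23_p5_absent", "Der p 20=1",
      "Der f 2=0,Der p 1=0,Der p 23=0,Der p 5=0"),
    c("derp1_given_p21_p5_p7_present", "Der p 1=1",
      "Der p 21=1,Der p 5=1,Der p 7=1"),
    c("derp1_absent_given_p21_p5_p7_absent", "Der p 1=0",
      "Der p 21=0,Der p 5=0,Der p 7=0"),
    c("derp21_marginal", "Der p 21=1", ""),
    c("derp5_given_p21_present", "Der p 5=1", "Der p 21=1"),
    c("derp5_absent_given_p21_absent", "Der p 5=0", "Der p 21=0"),
    c("derp7_absent_given_p21_p5_absent", "Der p 7=0",
      "Der p 21=0,Der p 5=0")
  )
  data.frame(name = q[, 1], target = q[, 2], evidence = q[, 3],
             stringsAsFactors = FALSE)
}

#' Pipeline run configuration
#'
#' Collects every setting of [run_pipeline()] into one validated,
#' YAML-serializable object. Either `input` (a panel file) or `simulate`
#' (settings for [generate_cohort()]) must be given.
#'
#' @param input optional path to a panel CSV/TSV.
#' @param delim input delimiter.
#' @param simulate optional list: `n` patients and optional fixture `name`
#'   (default `"paper11"`); used when `input` is `NULL`.
#' @param threshold sensitization threshold (kU/L).
#' @param child_cutoff child/adult age boundary (years).
#' @param bands age-band cutpoints for the age profile.
#' @param method structure learner, `"hc"` or `"chowliu"`.
#' @param root root node (no incoming edges for `"hc"`, orientation root for
#'   `"chowliu"`); `NULL` or `NA` for unconstrained hill climbing.
#' @param alpha CPT pseudocount.
#' @param max_parents hill-climbing in-degree cap.
#' @param queries data frame like [default_cpd_queries()], or a path to a
#'   CSV with the same columns.
#' @param seed RNG seed for the whole run.
#' @return a `run_config`.
#' @export
run_config <- function(input = NULL, delim = ",", simulate = NULL,
                       threshold = 0.31, child_cutoff = 18,
                       bands = c(1, 3, 6, 12, 18, 25, 36, 44, 60),
                       method = c("hc", "chowliu"), root = "Der p 23",
                       alpha = 1, max_parents = 4,
                       queries = default_cpd_queries(), seed = 1L) {
  method <- match.arg(method)
  if (is.null(input) && is.null(simulate)) {
    stop("either 'input' or 'simulate' must be given")
  }
  if (!is.null(simulate)) {
    simulate$name <- simulate$name %||% "paper11"
    if (is.null(simulate$n)) stop("'simulate$n' is required")
  }
  if (is.character(queries)) {
    queries <- read.table(queries, sep = ",", header = TRUE,
                          stringsAsFactors = FALSE)
  }
  if (!all(c("name", "target", "evidence") %in% names(queries))) {
    stop("'queries' needs columns name, target, evidence")
  }
  if (length(root) && (is.na(root) || !nzchar(root))) root <- NULL
  structure(list(input = input, delim = delim, simulate = simulate,
                 threshold = threshold, child_cutoff = child_cutoff,
                 bands = bands, method = method, root = root, alpha = alpha,
                 max_parents = max_parents, queries = queries,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with fields named as in [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$queries)) {
    y$queries <- do.call(rbind, lapply(y$queries, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  }
  do.call(run_config, y)
}

config_as_yaml <- function(config) {
  c <- unclass(config)
  c$queries <- lapply(seq_len(nrow(c$queries)),
                      function(i) as.list(c$queries[i, ]))
  yaml::as.yaml(c)
}

round_pct <- function(p) round_half_out(100 * p, 2)

#' Run the full analysis pipeline
#'
#' Reads (or simulates) a panel, binarizes it at the threshold, restricts to
#' sensitized patients, and writes seven artifacts into `outdir`:
#' `summary.json` (cohort summary), `table1.tsv` (per-component counts,
#' shares and sIgE summaries), `age_profile.tsv` (band-by-component
#' sensitization frequencies), `net.json` and `net.dot` (the learned
#' network), `cpd_results.json` (all requested conditional-probability
#' queries, as percentages with 2 decimals plus full-precision values), and
#' `run.log`. Identical config + seed give byte-identical artifacts. Any
#' stage failure aborts with the stage named and removes partial outputs.
#'
#' @param config a [run_config()] (or path to a YAML file).
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory results and artifact paths.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop("'config' must be a run_config")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("summary.json", "table1.tsv",
                               "age_profile.tsv", "net.json", "net.dot",
                               "cpd_results.json", "run.log",
                               "run_config.yaml"))
  names(paths) <- basename(paths)
  log_lines <- character(0)
  stage <- "setup"
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  res <- tryCatch({
    stage <- "input"
    if (!is.null(config$input)) {
      panel <- read_panel(config$input, delim = config$delim)
      note("input: read ", nrow(panel), " patients from ", config$input)
    } else {
      cc <- cohort_config(n_patients = config$simulate$n,
                          truth_net = config$simulate$name,
                          threshold = config$threshold, seed = config$seed)
      panel <- generate_cohort(cc)
      note("input: simulated ", nrow(panel), " patients from fixture '",
           config$simulate$name, "' (seed ", config$seed, ")")
    }

    stage <- "binarize"
    m_all <- binarize(panel, config$threshold)
    m <- filter_sensitized(m_all)
    note("binarize: threshold ", config$threshold, " kU/L; ", nrow(m$x),
         " of ", nrow(m_all$x), " patients sensitized")
    if (nrow(m$x) == 0) stop("no sensitized patients at this threshold")

    stage <- "summarize"
    summ <- cohort_summary(panel, m, child_cutoff = config$child_cutoff)
    jsonlite::write_json(summary_as_list(summ), paths["summary.json"],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    write_table1_tsv(summ, paths["table1.tsv"])
    prof <- group_frequency_table(m, age_bands(config$bands))
    write_age_profile_tsv(prof, paths["age_profile.tsv"])
    note("summarize: wrote summary.json, table1.tsv, age_profile.tsv")

    stage <- "learn"
    if (config$method == "hc") {
      dag <- learn_structure_hc(m, root = config$root,
                                max_parents = config$max_parents,
                                seed = config$seed)
    } else {
      dag <- learn_structure_chowliu(m, root = config$root %||%
                                       m$components[1])
    }
    net <- fit_cpds(dag, m, alpha = config$alpha)
    write_net_json(net, paths["net.json"])
    export_dag_dot(net, paths["net.dot"])
    note("learn: method ", config$method, ", ", nrow(dag_edges(dag)),
         " edges, alpha ", config$alpha)

    stage <- "query"
    qres <- lapply(seq_len(nrow(config$queries)), function(i) {
      row <- config$queries[i, ]
      r <- query(net, row$target, row$evidence)
      list(name = row$name, target = row$target, evidence = row$evidence,
           probability = if (r$undefined) NA_real_ else r$probability,
           percent = if (r$undefined) NA_real_ else round_pct(r$probability),
           support_count = r$support_count, undefined = r$undefined)
    })
    jsonlite::write_json(qres, paths["cpd_results.json"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    note("query: ", length(qres), " queries, ",
         sum(vapply(qres, `[[`, TRUE, "undefined")), " undefined")

    stage <- "log"
    writeLines(config_as_yaml(config), paths["run_config.yaml"])
    writeLines(log_lines, paths["run.log"])
    list(panel = panel, matrix = m, summary = summ, profile = prof,
         net = net, queries = qres, paths = paths)
  }, error = function(e) {
    unlink(paths[file.exists(paths)])
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

summary_as_list <- function(summ) {
  comp <- summ$components
  list(
    totals = summ$totals,
    stratum_denominator = summ$stratum_denominator,
    components = lapply(seq_len(nrow(comp)), function(i) as.list(comp[i, ]))
  )
}

tsv_num <- function(x, digits = 2) {
  out <- sprintf(paste0("%.", digits, "f"), round_half_out(x, digits))
  out[is.na(x)] <- "NA"
  out
}

# One row per component: counts, shares and mean +/- SD sIgE for the whole
# sensitized sample, children and adults. Every number is recomputable from
# summary.json (shares/means are re-serialized, not re-derived).
write_table1_tsv <- function(summ, path) {
  comp <- summ$components
  df <- data.frame(
    component = comp$component,
    sige_mean_sd = paste0(tsv_num(comp$mean_sige_all), " +/- ",
                          tsv_num(comp$sd_sige_all)),
    n = comp$n_all,
    share_pct = tsv_num(comp$share_all),
    sige_mean_sd_children = paste0(tsv_num(comp$mean_sige_children), " +/- ",
                                   tsv_num(comp$sd_sige_children)),
    n_children = comp$n_children,
    share_children_pct = tsv_num(comp$share_children),
    sige_mean_sd_adults = paste0(tsv_num(comp$mean_sige_adults), " +/- ",
                                 tsv_num(comp$sd_sige_adults)),
    n_adults = comp$n_adults,
    share_adults_pct = tsv_num(comp$share_adults),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write_tsv_file(df, path)
}

write_age_profile_tsv <- function(prof, path) {
  df <- data.frame(band = rownames(prof$freq_within_band),
                   n = as.integer(prof$band_sizes),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (k in colnames(prof$freq_within_band)) {
    df[[paste0(k, " (% of band)")]] <- tsv_num(prof$freq_within_band[, k])
    df[[paste0(k, " (% of total)")]] <- tsv_num(prof$freq_of_total[, k])
  }
  write_tsv_file(df, path)
}

write_tsv_file <- function(df, path) {
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(lapply(df, as.character), sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
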