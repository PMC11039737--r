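## Command-line pipeline orchestration: geometry audit, screening,
## drug-likeness filtration, validation, consensus generation and synthetic
## benchmark export. Every output file carries a provenance header
## (tool version, config hash, seed). A thin dispatcher script lives at
## inst/cli/phorescreen.

pkg_version <- function() {
  as.character(utils::packageVersion("phorescreen"))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

provenance_for <- function(config) {
  c(tool = paste0("phorescreen ", pkg_version()),
    config = config_hash(config),
    seed = as.character(if (is.null(config$seed)) NA else config$seed))
}

resolve_model <- function(model_ref) {
  if (is.null(model_ref) || identical(model_ref, "builtin"))
    return(builtin_dual_model())
  if (inherits(model_ref, "pharmacophore")) return(model_ref)
  read_pharmacophore(model_ref)
}

load_library_input <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.(jsonl|jsl)$", path)) return(list(kind = "features",
                                                  data = read_feature_sets(path)))
  if (grepl("\\.(smi|smiles)$", path)) return(list(kind = "molecules",
                                                   data = read_smiles(path)))
  list(kind = "molecules", data = read_sdf(path))
}

write_tsv_with_header <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the geometry audit stage
#'
#' Writes the inter-feature distance/angle table of a model (distances
#' rounded to 2 dp, angles to 1 dp in the file; full precision returned).
#'
#' @param config list with elements \code{model} (path or \code{"builtin"}),
#'   \code{out} (output TSV path) and optionally \code{seed}.
#' @return The geometry report data.frame, invisibly.
#' @export
run_geometry <- function(config) {
  model <- resolve_model(config$model)
  rep_ <- geometry_report(model)
  out_df <- rep_
  out_df$value <- ifelse(out_df$kind == "distance",
                         round(out_df$value, 2), round(out_df$value, 1))
  if (!is.null(config$out))
    write_tsv_with_header(out_df, config$out, provenance_for(config))
  invisible(rep_)
}

#' Run screening (and optional filtering and validation)
#'
#' The full analysis chain: load or perceive feature sets, match against
#' the model, optionally apply the drug-likeness filter (molecule input
#' only), and when labels are given compute the validation statistics.
#' Stage record counts (screened / hits / filter survivors) are logged via
#' \code{message()}.
#'
#' @param config list with elements \code{library} (SDF, SMILES or
#'   JSON-lines feature-set path), \code{model}, \code{out_screen},
#'   optional \code{labels} (TSV path or data.frame), \code{out_metrics},
#'   \code{filter} (logical), \code{out_filter}, \code{seed}, and matching
#'   parameters \code{min_match}, \code{radius_scale}, \code{pair_slack}.
#' @return list with \code{screening}, and when computed \code{filter} and
#'   \code{metrics}.
#' @export
run_screen_validate <- function(config) {
  model <- resolve_model(config$model)
  params <- match_params(
    min_match = config$min_match,
    radius_scale = if (is.null(config$radius_scale)) 1.0 else config$radius_scale,
    pair_slack = if (is.null(config$pair_slack)) 1.0 else config$pair_slack)
  input <- load_library_input(config$library)
  prov <- provenance_for(config)

  tab <- if (input$kind == "features")
    screen_features(input$data, model, params)
  else screen_library(input$data, model, params)
  message(sprintf("screen: %d records in, %d hits, %d errors",
                  nrow(tab), sum(tab$hit), sum(tab$error)))
  if (!is.null(config$out_screen))
    write_tsv_with_header(tab, config$out_screen, prov)
  out <- list(screening = tab)

  if (isTRUE(config$filter) && input$kind == "molecules") {
    parsed <- Filter(function(m) inherits(m, "molecule3d"), input$data)
    dl <- druglikeness_table(parsed)
    hits <- tab$molecule_id[tab$hit]
    dl <- dl[dl$molecule_id %in% hits, , drop = FALSE]
    message(sprintf("filter: %d hits in, %d drug-like", nrow(dl), sum(dl$pass)))
    if (!is.null(config$out_filter))
      write_tsv_with_header(dl, config$out_filter, prov)
    out$filter <- dl
  }

  if (!is.null(config$labels)) {
    labels <- config$labels
    if (is.character(labels))
      labels <- utils::read.delim(labels, comment.char = "#",
                                  stringsAsFactors = FALSE)
    metrics <- metrics_from_counts(counts_from_screen(labels, tab))
    if (!is.null(config$out_metrics))
      write_tsv_with_header(as.data.frame(metrics), config$out_metrics, prov)
    out$metrics <- metrics
  }
  out
}

#' Run the drug-likeness filter stage on a library
#'
#' @param config list with \code{library} (SDF or SMILES path), \code{out},
#'   optional \code{max_violations}, \code{seed}.
#' @return The drug-likeness table, invisibly.
#' @export
run_filter <- function(config) {
  input <- load_library_input(config$library)
  stopifnot(input$kind == "molecules")
  parsed <- Filter(function(m) inherits(m, "molecule3d"), input$data)
  dl <- druglikeness_table(parsed,
                           max_violations = if (is.null(config$max_violations)) 1L
                           else config$max_violations)
  message(sprintf("filter: %d molecules in, %d pass", nrow(dl), sum(dl$pass)))
  if (!is.null(config$out))
    write_tsv_with_header(dl, config$out, provenance_for(config))
  invisible(dl)
}

#' Run consensus model generation from an aligned ensemble
#'
#' @param config list with \code{library} (multi-record SDF or JSON-lines
#'   feature sets sharing one frame), \code{out} (model JSON path),
#'   optional \code{threshold}, \code{tolerance}, \code{essential_threshold}.
#' @return The consensus \code{\link{pharmacophore}}, invisibly.
#' @export
run_consensus <- function(config) {
  input <- load_library_input(config$library)
  fsets <- if (input$kind == "features") input$data
  else lapply(Filter(function(m) inherits(m, "molecule3d"), input$data),
              perceive)
  cp <- consensus_params(
    threshold = if (is.null(config$threshold)) 0.5 else config$threshold,
    tolerance = if (is.null(config$tolerance)) 1.15 else config$tolerance,
    essential_threshold = if (is.null(config$essential_threshold)) 0.9
    else config$essential_threshold)
  model <- consensus_model(fsets, cp)
  if (!is.null(config$out)) write_pharmacophore(model, config$out)
  invisible(model)
}

#' Run the synthetic benchmark export stage
#'
#' @param config list with \code{out_features} (JSON-lines path),
#'   \code{out_labels} (TSV path), \code{seed} (mandatory) and any
#'   \code{\link{generator_params}} fields.
#' @return The \code{synthetic_benchmark}, invisibly.
#' @export
run_synth <- function(config) {
  if (is.null(config$seed)) stop("synth requires an explicit seed", call. = FALSE)
  take <- function(nm, default) if (is.null(config[[nm]])) default else config[[nm]]
  params <- generator_params(
    n_actives = take("n_actives", 56L), n_decoys = take("n_decoys", 207L),
    jitter_sd = take("jitter_sd", 0.2), dropout_prob = take("dropout_prob", 0.3),
    decoy_mode = take("decoy_mode", "mixed"),
    inflate_factor = take("inflate_factor", 3),
    kind_mode = take("kind_mode", "minimal"), seed = config$seed)
  bench <- make_benchmark(resolve_model(config$model), params)
  if (!is.null(config$out_features))
    write_feature_sets(bench$feature_sets, config$out_features)
  if (!is.null(config$out_labels))
    write_tsv_with_header(bench$labels, config$out_labels,
                          provenance_for(config))
  invisible(bench)
}

## ---- command-line dispatcher --------------------------------------------

cli_usage <- function() {
  paste(
    "usage: phorescreen <subcommand> [--config file.yaml] [--key value ...]",
    "",
    "subcommands:",
    "  geometry   --model builtin|model.json --out geometry.tsv",
    "  screen     --library lib.sdf|lib.smi|sets.jsonl --model builtin",
    "             --out-screen screen.tsv [--labels labels.tsv --out-metrics m.tsv]",
    "             [--filter --out-filter filtered.tsv]",
    "  filter     --library lib.sdf --out druglike.tsv",
    "  validate   --labels labels.tsv --screening screen.tsv --out metrics.tsv",
    "  consensus  --library aligned.sdf|sets.jsonl --out model.json",
    "  synth      --seed N --out-features sets.jsonl --out-labels labels.tsv",
    "",
    "Options may also be given in a YAML config file; command-line flags win.",
    sep = "\n")
}

parse_cli_args <- function(args) {
  config <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", substring(a, 3L))
    nxt <- if (i + 1L <= length(args)) args[[i + 1L]] else NULL
    if (is.null(nxt) || startsWith(nxt, "--")) {
      config[[key]] <- TRUE
      i <- i + 1L
    } else {
      num <- suppressWarnings(as.numeric(nxt))
      config[[key]] <- if (!is.na(num)) num else nxt
      i <- i + 2L
    }
  }
  config
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (\code{geometry}, \code{screen},
#' \code{filter}, \code{validate}, \code{consensus}, \code{synth}); used by
#' the \code{inst/cli/phorescreen} script. Options come from an optional
#' YAML config file (\code{--config}) overridden by \code{--key value}
#' flags.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
phore_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[[1L]] %in% c("-h", "--help", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(0L))
  }
  sub <- args[[1L]]
  status <- tryCatch({
    config <- parse_cli_args(args[-1L])
    if (!is.null(config$config)) {
      file_cfg <- yaml::read_yaml(config$config)
      for (k in setdiff(names(file_cfg), names(config)))
        config[[k]] <- file_cfg[[k]]
    }
    switch(sub,
      geometry = run_geometry(config),
      screen = run_screen_validate(config),
      filter = run_filter(config),
      validate = {
        labels <- utils::read.delim(config$labels, comment.char = "#",
                                    stringsAsFactors = FALSE)
        tab <- read_screening_tsv(config$screening)
        metrics <- metrics_from_counts(counts_from_screen(labels, tab))
        print(metrics)
        if (!is.null(config$out))
          write_tsv_with_header(as.data.frame(metrics), config$out,
                                provenance_for(config))
        metrics
      },
      consensus = run_consensus(config),
      synth = run_synth(config),
      stop("unknown subcommand: ", sub, call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
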