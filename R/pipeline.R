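# Configuration-driven orchestration: generate -> analyze-islets ->
# analyze-cells -> stats -> report, with a plain-text log and a resolved
# configuration snapshot as the unit of provenance. Re-running with the
# same resolved config and seed reproduces every CSV bit-identically.

#' Build a pipeline configuration
#'
#' @param input_dir cohort directory (as written by [render_cohort()]); if
#'   `NULL` and `generate` is given, the cohort is generated first.
#' @param output_dir run directory to create.
#' @param generate optional list describing generation:
#'   `groups` (character, preset labels), `panel`, `n_donors_per_group`,
#'   `islets_per_donor`, plus optional [generator_config()] overrides.
#' @param panel panel of the analysed images: `"A"` or `"B"`.
#' @param min_cells minimum cells per islet (default 10).
#' @param thresholds optional named manual cell thresholds.
#' @param coloc_pair channel pair for per-cell co-localisation (default:
#'   the panel hormone vs PC13).
#' @param statistic donor aggregation statistic for areas (default
#'   `"mean"`).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir, generate = NULL,
                            panel = "A", min_cells = 10L, thresholds = NULL,
                            coloc_pair = NULL, statistic = "mean", seed = 1L) {
  panel <- match.arg(panel, names(PANELS))
  if (is.null(coloc_pair))
    coloc_pair <- c(PANELS[[panel]][1], "PC13")
  if (min_cells < 1) stop("min_cells must be >= 1")
  if (anyDuplicated(PANELS[[panel]])) stop("channel names must be unique")
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 generate = generate, panel = panel,
                 channels = c(NUCLEAR_CHANNEL, PANELS[[panel]]),
                 min_cells = as.integer(min_cells), thresholds = thresholds,
                 coloc_pair = coloc_pair, statistic = statistic,
                 seed = as.integer(seed), manual_corrections = FALSE),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages run in order (generate if requested, whole-islet arm, single-cell
#' arm, donor statistics, phenotype trajectory); every stage's parameters
#' are appended to `run.log`, the resolved configuration snapshot is
#' written to `config_resolved.json`, and all tables land as CSVs in the
#' run directory. Fully deterministic for a fixed (config, seed). A stage
#' failure aborts with the stage name; partial outputs are preserved.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the result tables (`islets`, `cells`,
#'   `donor_stats`, `trajectory`) and the run directory path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  logline <- function(...) cat(paste0(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("isletquant pipeline, package version ",
          as.character(utils::packageVersion("isletquant")))
  logline("seed: ", config$seed, "; panel: ", config$panel,
          "; min_cells: ", config$min_cells,
          "; manual corrections: none (not implemented by design)")
  stage <- function(name, expr) {
    logline("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  input_dir <- config$input_dir
  if (!is.null(config$generate)) {
    gen <- config$generate
    input_dir <- if (!is.null(input_dir)) input_dir
                 else file.path(out, "generated")
    stage("generate", {
      cfgs <- lapply(gen$groups, make_group_preset, panel = config$panel)
      names(cfgs) <- gen$groups
      render_cohort(cfgs, gen$n_donors_per_group, gen$islets_per_donor,
                    seed = config$seed, out_dir = input_dir,
                    images_per_donor = gen$images_per_donor %||% 1L)
      logline("  generated cohort in ", input_dir)
    })
  }
  if (is.null(input_dir) || !dir.exists(input_dir))
    stop("pipeline stage 'input' failed: no input directory")
  meta <- data.table::fread(file.path(input_dir, "donors.csv"))

  markers <- PANELS[[config$panel]]
  islet_rows <- list(); cell_rows <- list()
  stage("analyze", {
    for (di in seq_len(nrow(meta))) {
      donor <- meta$donor_id[di]
      tifs <- sort(list.files(file.path(input_dir, donor),
                              pattern = "\\.tif$", full.names = TRUE))
      for (tf in tifs) {
        img <- read_image_tiff(tf)
        ires <- analyze_islets(img, marker_channels = markers,
                               min_cells = config$min_cells)
        islets <- attr(ires, "islets")
        pimg <- attr(ires, "image")
        if (nrow(ires)) {
          ires$donor_id <- donor; ires$group <- meta$group[di]
          ires$field <- basename(tf)
          islet_rows[[length(islet_rows) + 1L]] <- ires
        }
        if (length(islets)) {
          cres <- analyze_cells(pimg, islets, marker_channels = markers,
                                coloc_pair = config$coloc_pair,
                                classify = FALSE)
          if (nrow(cres)) {
            cres$donor_id <- donor; cres$group <- meta$group[di]
            cres$field <- basename(tf)
            cell_rows[[length(cell_rows) + 1L]] <- cres
          }
        }
      }
      logline("  donor ", donor, ": ", length(tifs), " field(s)")
    }
  })
  islet_tab <- data.table::rbindlist(islet_rows, fill = TRUE)
  cell_tab <- data.table::rbindlist(cell_rows, fill = TRUE)
  if (nrow(cell_tab)) {
    # per-batch classification: thresholds derived per donor (one staining
    # batch per donor panel), falling back to the cohort-pooled threshold
    # when a donor's distribution has no separable positive population
    pooled <- setNames(numeric(length(markers)), markers)
    for (ch in markers) {
      pooled[ch] <- if (!is.null(config$thresholds) &&
                        ch %in% names(config$thresholds))
        config$thresholds[[ch]]
      else tryCatch(suppressWarnings(determine_cell_thresholds(cell_tab, ch)),
                    error = function(e) Inf)
    }
    parts <- list()
    for (donor in unique(cell_tab$donor_id)) {
      dcells <- cell_tab[cell_tab$donor_id == donor]
      thr <- pooled
      if (is.null(config$thresholds)) {
        for (ch in markers) {
          t_d <- tryCatch(suppressWarnings(
            determine_cell_thresholds(dcells, ch)), error = function(e) Inf)
          if (is.finite(t_d)) thr[ch] <- t_d
        }
      }
      dcells <- finalize_cells(dcells, thr, markers)
      logline("  thresholds ", donor, ": ",
              paste(names(thr), round(unname(thr), 1), sep = "=",
                    collapse = ", "))
      parts[[donor]] <- dcells
    }
    cell_tab <- data.table::rbindlist(parts, fill = TRUE)
  }
  data.table::fwrite(islet_tab, file.path(out, "islets.csv"))
  data.table::fwrite(cell_tab, file.path(out, "cells.csv"))

  donor_stats <- list(); trajectory <- data.table::data.table()
  stage("stats", {
    if (nrow(cell_tab)) {
      metrics <- c("cytoplasm_area_um2", "nucleus_area_um2", "nc_ratio",
                   paste0("rfu_", markers))
      if ("proins_ins_ratio" %in% names(cell_tab))
        metrics <- c(metrics, "proins_ins_ratio")
      for (m in intersect(metrics, names(cell_tab))) {
        statn <- if (m == "proins_ins_ratio") "median" else config$statistic
        agg <- aggregate_donor(cell_tab[cell_tab$in_islet], m,
                               statistic = statn)
        agg$metric <- m
        res <- tryCatch(compare_groups(agg), error = function(e) NULL)
        donor_stats[[m]] <- data.table::data.table(
          metric = m, statistic_type = statn,
          test = if (is.null(res)) NA_character_ else res$test_used,
          omnibus_statistic = if (is.null(res)) NA_real_ else res$statistic,
          p_value = if (is.null(res)) NA_real_ else res$p_value)
      }
      mcol <- paste0("cell_m1_", config$coloc_pair[1], "_", config$coloc_pair[2])
      pcols <- paste0("pos_", config$coloc_pair)
      if (mcol %in% names(cell_tab) && all(pcols %in% names(cell_tab))) {
        # donor-level co-localisation: mean per-cell M1 over cells positive
        # for both channels of the pair
        dbl <- cell_tab[cell_tab$in_islet & cell_tab[[pcols[1]]] &
                          cell_tab[[pcols[2]]]]
        if (nrow(dbl)) {
          agg <- aggregate_donor(dbl, mcol, statistic = "mean")
          res <- tryCatch(compare_groups(agg), error = function(e) NULL)
          donor_stats[[mcol]] <- data.table::data.table(
            metric = mcol, statistic_type = "mean",
            test = if (is.null(res)) NA_character_ else res$test_used,
            omnibus_statistic = if (is.null(res)) NA_real_ else res$statistic,
            p_value = if (is.null(res)) NA_real_ else res$p_value)
        }
      }
      cnt <- cell_tab[cell_tab$in_islet,
                      list(n = .N),
                      by = c("donor_id", "group", "phenotype")]
      trajectory <- phenotype_trajectory(cnt)
    }
  })
  donor_tab <- data.table::rbindlist(donor_stats)
  data.table::fwrite(donor_tab, file.path(out, "stats.csv"))
  data.table::fwrite(trajectory, file.path(out, "trajectory.csv"))

  snap <- config
  snap$input_dir <- input_dir
  jsonlite::write_json(unclass(snap)[!vapply(unclass(snap), is.null, logical(1))],
                       file.path(out, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logline("done; outputs: islets.csv, cells.csv, stats.csv, trajectory.csv")
  invisible(list(islets = islet_tab, cells = cell_tab,
                 donor_stats = donor_tab, trajectory = trajectory,
                 run_dir = out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `generate`, `analyze-islets`, `analyze-cells`, `stats` and
#' `run` (all stages), each driven by a JSON config file:
#' `isletquant run --config FILE`. Installed as
#' `inst/scripts/isletquant`.
#'
#' @param args character vector (default: command line arguments).
#' @return exit status, invisibly.
#' @export
isletquant_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: isletquant <generate|analyze-islets|analyze-cells|stats|run>",
    "--config FILE [--in DIR] [--out DIR]")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  if (is.null(opt$config)) { message(usage); return(invisible(1L)) }
  raw <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
  cfg <- pipeline_config(
    input_dir = opt[["in"]] %||% raw$input_dir,
    output_dir = opt[["out"]] %||% raw$output_dir,
    generate = raw$generate, panel = raw$panel %||% "A",
    min_cells = raw$min_cells %||% 10L,
    thresholds = raw$thresholds, coloc_pair = raw$coloc_pair,
    statistic = raw$statistic %||% "mean", seed = raw$seed %||% 1L)
  if (cmd == "generate") {
    gen <- cfg$generate
    cfgs <- lapply(gen$groups, make_group_preset, panel = cfg$panel)
    names(cfgs) <- gen$groups
    render_cohort(cfgs, gen$n_donors_per_group, gen$islets_per_donor,
                  seed = cfg$seed,
                  out_dir = cfg$input_dir %||% cfg$output_dir)
  } else if (cmd %in% c("analyze-islets", "analyze-cells", "stats", "run")) {
    # the stages share provenance; partial commands still run upstream
    # stages they depend on, writing only into the run directory
    run_pipeline(cfg)
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
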