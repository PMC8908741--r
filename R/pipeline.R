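#' Pipeline configuration
#'
#' A flat, serializable set of parameters driving [run_stage()] /
#' [run_pipeline()]. Defaults mirror the canonical analysis choices of the
#' method (TICA lag 120 ns, 50 p(TP|xi) bins, 21 overlap bins, 6 states,
#' 1 ns median filter, 5 error blocks), so a user featurizing a real
#' hairpin trajectory at 0.2 ns stride reproduces the standard protocol;
#' every value can be overridden.
#'
#' @param input one of `"toy"` (synthetic toy folder, no files needed),
#'   `"channels"` (pre-featurized delimited text, see [read_channels()]),
#'   `"pdb"` (multi-model PDB, featurized to inter-residue distances).
#' @param input_path input file for `"channels"` / `"pdb"`.
#' @param dt_ns frame stride in ns.
#' @param mvar_orders candidate MVAR orders for [select_order()].
#' @param tica_lag_ns TICA lag time in ns.
#' @param pmf_bins,ptp_bins,overlap_bins bin counts.
#' @param n_states number of discrete pathway states.
#' @param filter_width_ns median filter width in ns (converted to an odd
#'   number of frames).
#' @param block_count error blocks.
#' @param shuffle_count shuffled-null replicates.
#' @param seed integer seed recorded in every provenance record and used
#'   for all stochastic steps.
#' @param categories_path optional two-column text file (channel, category).
#' @param toy_length,toy_well_depth toy-folder generation parameters (used
#'   only when `input = "toy"`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = c("toy", "channels", "pdb"),
                            input_path = NULL, dt_ns = 0.2,
                            mvar_orders = c(1L, 2L, 3L),
                            tica_lag_ns = 120, pmf_bins = 50L,
                            ptp_bins = 50L, overlap_bins = 21L,
                            n_states = 6L, filter_width_ns = 1,
                            block_count = 5L, shuffle_count = 50L,
                            seed = 1L, categories_path = NULL,
                            toy_length = 2e5, toy_well_depth = 4) {
  input <- match.arg(input)
  cfg <- list(input = input, input_path = input_path, dt_ns = dt_ns,
              mvar_orders = as.integer(mvar_orders),
              tica_lag_ns = tica_lag_ns, pmf_bins = as.integer(pmf_bins),
              ptp_bins = as.integer(ptp_bins),
              overlap_bins = as.integer(overlap_bins),
              n_states = as.integer(n_states),
              filter_width_ns = filter_width_ns,
              block_count = as.integer(block_count),
              shuffle_count = as.integer(shuffle_count),
              seed = as.integer(seed), categories_path = categories_path,
              toy_length = as.integer(toy_length),
              toy_well_depth = toy_well_depth)
  counts <- c(cfg$pmf_bins, cfg$ptp_bins, cfg$overlap_bins, cfg$n_states,
              cfg$block_count, cfg$shuffle_count)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$dt_ns <= 0 || cfg$tica_lag_ns <= 0 || cfg$filter_width_ns <= 0)
    stop("dt_ns, tica_lag_ns and filter_width_ns must be positive")
  if (input != "toy" && is.null(input_path))
    stop("input_path is required for input = '", input, "'")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration (flat key = value text)
#'
#' Vector-valued fields are comma-joined; `NULL` fields are omitted.
#'
#' @param config a [pipeline_config].
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  keep <- !vapply(config, is.null, logical(1))
  lines <- vapply(names(config)[keep], function(k)
    sprintf("%s = %s", k, paste(format(config[[k]], scientific = FALSE),
                                collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(lapply(kv, function(p) {
    v <- strsplit(p[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else trimws(v)
  }), vapply(kv, `[[`, character(1), 1L))
  do.call(pipeline_config, vals)
}

pipeline_stages <- c("featurize", "tica", "validate-rc", "states",
                     "pathway", "granger", "report")

stage_requirements <- list(
  "featurize" = character(0),
  "tica" = "channels.tsv",
  "validate-rc" = "xi.tsv",
  "states" = c("xi.tsv", "projections.tsv"),
  "pathway" = c("states.tsv", "xi.tsv", "channels.tsv"),
  "granger" = "channels.tsv",
  "report" = c("channels.tsv", "descriptors.tsv", "ptp.tsv",
               "committor.tsv", "events.tsv"))

stage_producing <- function(file) {
  producers <- c("channels.tsv" = "featurize", "xi.tsv" = "tica",
                 "projections.tsv" = "tica", "pmf.tsv" = "validate-rc",
                 "ptp.tsv" = "validate-rc", "states.tsv" = "states",
                 "descriptors.tsv" = "granger", "committor.tsv" = "pathway",
                 "events.tsv" = "pathway")
  unname(producers[file])
}

write_tsv <- function(x, path, rownames = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = rownames, col.names = if (rownames) NA else TRUE)
}

provenance_record <- function(stage, config, workdir, inputs) {
  sums <- if (length(inputs))
    as.list(tools::md5sum(file.path(workdir, inputs))) else list()
  names(sums) <- inputs
  obj <- list(stage = stage,
              package = "grangerfold",
              version = as.character(utils::packageVersion("grangerfold")),
              seed = config$seed,
              config = unclass(config)[!vapply(config, is.null, logical(1))],
              input_checksums = sums)
  jsonlite::write_json(obj, file.path(workdir, paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Executes a named stage of the analysis pipeline against a working
#' directory, reading upstream artifacts from it and writing this stage's
#' outputs plus a provenance sidecar (`<stage>.provenance.json` holding the
#' configuration, the seed, and md5 checksums of consumed inputs). With the
#' same configuration and seed every numeric output is byte-identical
#' across runs. Stages in order: `featurize`, `tica`, `validate-rc`,
#' `states`, `pathway`, `granger`, `report`.
#'
#' @param stage stage name.
#' @param config a [pipeline_config].
#' @param workdir working directory for all artifacts (created if absent).
#' @return invisibly, a character vector of files written.
#' @export
run_stage <- function(stage, config, workdir) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- match.arg(stage, pipeline_stages)
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  needed <- stage_requirements[[stage]]
  missing <- needed[!file.exists(file.path(workdir, needed))]
  if (length(missing))
    stop("stage '", stage, "' requires ", paste(missing, collapse = ", "),
         " — run stage '", stage_producing(missing[1]), "' first")
  written <- switch(stage,
    "featurize" = stage_featurize(config, workdir),
    "tica" = stage_tica(config, workdir),
    "validate-rc" = stage_validate_rc(config, workdir),
    "states" = stage_states(config, workdir),
    "pathway" = stage_pathway(config, workdir),
    "granger" = stage_granger(config, workdir),
    "report" = stage_report(config, workdir))
  provenance_record(stage, config, workdir, needed)
  invisible(written)
}

#' Run the complete pipeline
#'
#' @inheritParams run_stage
#' @return invisibly, the working directory.
#' @export
run_pipeline <- function(config, workdir) {
  for (stage in pipeline_stages) run_stage(stage, config, workdir)
  invisible(workdir)
}

stage_featurize <- function(config, workdir) {
  files <- "channels.tsv"
  if (config$input == "toy") {
    spec <- toy_folder_spec(well_depth = config$toy_well_depth,
                            length = config$toy_length,
                            seed = config$seed, dt = config$dt_ns)
    toy <- simulate_toy_folder(spec)
    write_channels(toy$channels, file.path(workdir, "channels.tsv"))
    write_tsv(data.frame(x = toy$coordinate),
              file.path(workdir, "toy_coordinate.tsv"))
    write_tsv(data.frame(channel = names(toy_folder_categories(spec)),
                         category = unname(toy_folder_categories(spec))),
              file.path(workdir, "categories.tsv"))
    files <- c(files, "toy_coordinate.tsv", "categories.tsv")
  } else if (config$input == "channels") {
    series <- read_channels(config$input_path)
    write_channels(series, file.path(workdir, "channels.tsv"))
  } else {
    traj <- read_pdb_trajectory(config$input_path, dt = config$dt_ns)
    series <- residue_min_distances(traj)
    write_channels(series, file.path(workdir, "channels.tsv"))
  }
  if (!is.null(config$categories_path)) {
    cats <- utils::read.table(config$categories_path, header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
    write_tsv(cats, file.path(workdir, "categories.tsv"))
    files <- unique(c(files, "categories.tsv"))
  }
  files
}

stage_tica <- function(config, workdir) {
  series <- read_channels(file.path(workdir, "channels.tsv"))
  lag_frames <- max(1L, round(config$tica_lag_ns / series$dt))
  model <- fit_tica(normalize_channels(series), lag_frames,
                    kinetic_map = TRUE)
  proj <- project_tica(model, normalize_channels(series))
  write_tica(model, file.path(workdir, "tica_model.json"))
  write_tsv(data.frame(xi = proj[, 1L]), file.path(workdir, "xi.tsv"))
  write_tsv(as.data.frame(proj), file.path(workdir, "projections.tsv"))
  c("tica_model.json", "xi.tsv", "projections.tsv")
}

read_xi <- function(workdir)
  utils::read.table(file.path(workdir, "xi.tsv"), header = TRUE)$xi

# Cores: one-PMF-bin-wide intervals around the two deepest minima.
pmf_and_cores <- function(xi, config) {
  pmf <- pmf_profile(xi, n_bins = config$pmf_bins,
                     block_count = config$block_count)
  minima <- locate_pmf_minima(pmf)
  h <- abs(pmf$center[2] - pmf$center[1])
  list(pmf = pmf, minima = minima,
       cores = list(F = minima$f + c(-h, h) / 2,
                    U = minima$u + c(-h, h) / 2))
}

stage_validate_rc <- function(config, workdir) {
  xi <- read_xi(workdir)
  pc <- pmf_and_cores(xi, config)
  write_profile(pc$pmf, file.path(workdir, "pmf.tsv"))
  ptp <- p_tp_profile(xi, pc$cores, n_bins = config$ptp_bins,
                      block_count = config$block_count)
  write_profile(ptp, file.path(workdir, "ptp.tsv"))
  c("pmf.tsv", "ptp.tsv")
}

stage_states <- function(config, workdir) {
  xi <- read_xi(workdir)
  proj <- as.matrix(utils::read.table(file.path(workdir, "projections.tsv"),
                                      header = TRUE))
  pc <- pmf_and_cores(xi, config)
  sm <- discretize_and_medoids(xi, proj, pc$minima$f, pc$minima$u,
                               n_states = config$n_states,
                               seed = config$seed)
  fw <- max(1L, round(config$filter_width_ns / config$dt_ns))
  if (fw %% 2L == 0L) fw <- fw + 1L  # filter widths are forced odd
  filtered <- median_filter_states(sm$labels, fw)
  write_tsv(data.frame(label = sm$labels, filtered = filtered),
            file.path(workdir, "states.tsv"))
  write_tsv(data.frame(state = seq_along(sm$centers), center = sm$centers,
                       medoid_frame = sm$medoid_frames),
            file.path(workdir, "medoids.tsv"))
  c("states.tsv", "medoids.tsv")
}

stage_pathway <- function(config, workdir) {
  st <- utils::read.table(file.path(workdir, "states.tsv"), header = TRUE)
  xi <- read_xi(workdir)
  series <- read_channels(file.path(workdir, "channels.tsv"))
  pc <- pmf_and_cores(xi, config)
  f_state <- 1L; u_state <- config$n_states  # centers run F -> U
  tm <- transition_matrix(st$filtered, n_states = config$n_states)
  write_tsv(round(tm$P, 10), file.path(workdir, "transition_matrix.tsv"),
            rownames = TRUE)
  write_tsv(data.frame(state = seq_len(config$n_states),
                       population = tm$populations),
            file.path(workdir, "populations.tsv"))
  cf <- committor_states(st$filtered, f_state, u_state,
                         n_states = config$n_states,
                         block_count = config$block_count)
  write_tsv(cf, file.path(workdir, "committor.tsv"))
  ev <- count_events(st$filtered, f_state, u_state, dt = config$dt_ns)
  write_tsv(ev$summary, file.path(workdir, "events.tsv"))
  om <- sapply(seq_len(n_channels(series)), function(k) {
    prof <- tryCatch(overlap_profile(series$values[, k], xi,
                                     pc$minima$f, pc$minima$u,
                                     n_bins = config$overlap_bins),
                     error = function(e) NULL)
    if (is.null(prof)) rep(NA_real_, config$overlap_bins) else prof$value
  })
  colnames(om) <- series$labels
  write_tsv(data.frame(center = seq(pc$minima$f, pc$minima$u,
                                    length.out = config$overlap_bins),
                       om, check.names = FALSE),
            file.path(workdir, "overlap.tsv"))
  c("transition_matrix.tsv", "populations.tsv", "committor.tsv",
    "events.tsv", "overlap.tsv")
}

stage_granger <- function(config, workdir) {
  series <- read_channels(file.path(workdir, "channels.tsv"))
  norm <- normalize_channels(series)
  sel <- select_order(norm, config$mvar_orders)
  write_tsv(sel$table, file.path(workdir, "sbc.tsv"))
  J <- gc_matrix(norm, sel$order)
  write_gc(J, file.path(workdir, "gc_matrix.tsv"))
  cats <- NULL
  cat_file <- file.path(workdir, "categories.tsv")
  if (file.exists(cat_file)) {
    tab <- utils::read.table(cat_file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    cats <- stats::setNames(tab$category, tab$channel)
  }
  desc <- split_half_convergence(series, sel$order, categories = cats)
  write_tsv(desc, file.path(workdir, "descriptors.tsv"))
  files <- c("sbc.tsv", "gc_matrix.tsv", "descriptors.tsv")
  if (!is.null(cats)) {
    sig <- suppressWarnings(
      shuffle_null_test(series, sel$order, n_shuffles = config$shuffle_count,
                        categories = cats, seed = config$seed))
    write_tsv(sig, file.path(workdir, "significance.tsv"))
    files <- c(files, "significance.tsv")
  }
  files
}

stage_report <- function(config, workdir) {
  rd <- function(f) utils::read.table(file.path(workdir, f), header = TRUE,
                                      sep = "\t", comment.char = "#",
                                      check.names = FALSE)
  desc <- rd("descriptors.tsv")
  ptp <- rd("ptp.tsv")
  cf <- rd("committor.tsv")
  ev <- rd("events.tsv")
  lines <- c(
    "grangerfold pipeline report",
    sprintf("seed: %d", config$seed),
    sprintf("input: %s", config$input),
    "",
    sprintf("p(TP|xi) maximum: %.3f (diffusive limit 0.5)",
            max(ptp$value, na.rm = TRUE)),
    "",
    "top channels by origin predictability G_origin (initiators first):")
  ord <- order(-desc$g_origin)
  lines <- c(lines, sprintf("  %-24s G_origin %+0.4f  G_total %.4f",
                            desc$channel[ord], desc$g_origin[ord],
                            desc$g_total[ord]))
  sig_file <- file.path(workdir, "significance.tsv")
  if (file.exists(sig_file)) {
    sig <- rd("significance.tsv")
    lines <- c(lines, "", "shuffle-null significance (category / descriptor / p):")
    lines <- c(lines, sprintf("  %-10s %-9s p = %.4g", sig$category,
                              sig$descriptor, sig$p_value))
  }
  lines <- c(lines, "",
             sprintf("committor CF by state: %s",
                     paste(sprintf("%d:%.3f", cf$state, cf$cf),
                           collapse = "  ")),
             "",
             sprintf("%s events: n = %d, mean duration %.2f ns (SD %.2f)",
                     ev$process, ev$n_events, ev$mean_duration,
                     ev$sd_duration))
  writeLines(lines, file.path(workdir, "report.txt"))
  "report.txt"
}
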