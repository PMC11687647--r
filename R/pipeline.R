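#' Default pipeline configuration
#'
#' The run configuration consumed by [run_pipeline()] and the command-line
#' wrapper. It can be written as YAML; [read_run_config()] merges a YAML
#' file over these defaults.
#'
#' @param seed Root seed for every source of randomness.
#' @return Nested list: `$seed`, `$J`, `$paths` (terminology, lexicon, log,
#'   out_dir), `$simulation` (passed to [simulation_config()]),
#'   `$analysis` (margin, confidence, s_max, sg_window, sg_polyorder,
#'   zones, idiom_s_cap, normalize_distance).
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    J = 30L,
    paths = list(terminology = NULL, lexicon = NULL, log = NULL,
                 out_dir = "."),
    simulation = list(n_users = 200L, n_labels = 300L, n_events = 50000L,
                      zipf_s = 1, epsilon0 = 0.8, decay = 0.85,
                      idiom_start_prob = 0.8, adaptation = TRUE,
                      adoption_rule = "pareto"),
    analysis = list(margin = 0.03, confidence = 0.95, s_max = NULL,
                    sg_window = 11L, sg_polyorder = 2L,
                    zones = c(5L, 10L), idiom_s_cap = 15L,
                    normalize_distance = FALSE)
  )
}

#' Read a YAML run configuration
#'
#' Values present in the file override the defaults; everything else keeps
#' its default. Unknown top-level keys are an error.
#'
#' @param path YAML file path.
#' @param seed Optional seed override (e.g. from the command line).
#' @return A configuration list as in [default_config()].
#' @export
read_run_config <- function(path = NULL, seed = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad) > 0) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    for (k in names(user)) {
      cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(user[[k]])) {
        utils::modifyList(cfg[[k]], user[[k]])
      } else {
        user[[k]]
      }
    }
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

stage_path <- function(cfg, file) file.path(cfg$paths$out_dir, file)

# hash of the scientific parameters only (paths are machine-local)
config_hash <- function(cfg) rlang::hash(cfg[setdiff(names(cfg), "paths")])

write_provenance <- function(cfg, stage, files) {
  prov <- list(stage = stage, seed = cfg$seed,
               config_hash = config_hash(cfg), files = basename(files),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, stage_path(cfg, paste0("provenance_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

load_inputs <- function(cfg) {
  trm_path <- cfg$paths$terminology %||% stage_path(cfg, "terminology.csv")
  lex_path <- cfg$paths$lexicon %||% stage_path(cfg, "lexicon.txt")
  log_path <- cfg$paths$log %||% stage_path(cfg, "log_raw.csv")
  for (p in c(trm_path, lex_path, log_path)) {
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
  }
  list(trm = read_terminology(trm_path),
       lexicon = read_idiom_lexicon(lex_path),
       log = read_log(log_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run pipeline stages
#'
#' Executes one stage (or `"all"`, which chains them) of the analysis:
#' `simulate` writes a synthetic terminology, idiom lexicon and raw log;
#' `enrich` adds qlen/seniority/rank; `pareto` computes per-label fronts
#' and distances; `adapt` writes representativeness and seniority curves;
#' `idioms` writes idiom-usage tables; `zipf` writes rank-frequency tables
#' and power-law fits; `report` writes a JSON summary of the headline
#' quantities. Every stage logs its parameters and seed to a sidecar
#' provenance file, and reruns with an identical configuration and seed
#' produce identical artifacts.
#'
#' @param stage One of `"simulate"`, `"enrich"`, `"pareto"`, `"adapt"`,
#'   `"idioms"`, `"zipf"`, `"report"`, `"all"`.
#' @param config Configuration list (see [default_config()]).
#' @return Invisibly, the list of files written.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "enrich", "pareto",
                                   "adapt", "idioms", "zipf", "report"),
                         config = default_config()) {
  stage <- match.arg(stage)
  cfg <- config
  dir.create(cfg$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    files <- unlist(lapply(
      c("simulate", "enrich", "pareto", "adapt", "idioms", "zipf", "report"),
      function(s) run_pipeline(s, cfg)
    ))
    return(invisible(files))
  }

  files <- character(0)
  if (stage == "simulate") {
    sim <- do.call(simulation_config,
                   c(cfg$simulation, list(J = cfg$J, seed = cfg$seed)))
    trm <- generate_terminology(sim$n_labels, cfg$seed)
    lex <- generate_idiom_lexicon(trm, cfg$seed)
    log <- simulate_log(sim, trm, lex)
    files <- c(write_terminology(trm, stage_path(cfg, "terminology.csv")),
               write_idiom_lexicon(lex, stage_path(cfg, "lexicon.txt")),
               write_log(log, stage_path(cfg, "log_raw.csv")))
  } else if (stage == "enrich") {
    inp <- load_inputs(cfg)
    enr <- enrich_log(inp$log, inp$trm, cfg$J)
    files <- write_log(enr, stage_path(cfg, "log_enriched.csv"))
  } else if (stage == "pareto") {
    inp <- load_inputs(cfg)
    enr <- read_enriched(cfg)
    fronts <- pareto_fronts(enr, inp$trm, cfg$J)
    dst <- annotate_distance(enr, fronts, cfg$analysis$normalize_distance)
    files <- c(write_fronts(fronts, stage_path(cfg, "fronts.csv")),
               write_log(dst, stage_path(cfg, "log_distance.csv")))
  } else if (stage == "adapt") {
    dst <- read_distance(cfg)
    rep <- representative_cap(dst, cfg$analysis$margin, cfg$analysis$confidence)
    readr::write_csv(rep$levels, stage_path(cfg, "representativeness.csv"))
    s_max <- cfg$analysis$s_max %||% max(1L, rep$s_max)
    s_max <- min(s_max, max(dst$seniority))
    flt <- consistency_filter(dst, s_max)
    files <- stage_path(cfg, "representativeness.csv")
    for (m in c("distance", "qlen", "rank")) {
      cur <- curve_by_seniority(flt, m, S_max = s_max)
      w <- min(cfg$analysis$sg_window,
               nrow(cur) - (1 - nrow(cur) %% 2))  # largest odd <= levels
      if (w > cfg$analysis$sg_polyorder) cur <- smooth_curve(cur, w, cfg$analysis$sg_polyorder)
      p <- stage_path(cfg, paste0("curve_", m, ".csv"))
      write_curve(cur, p)
      files <- c(files, p)
    }
  } else if (stage == "idioms") {
    inp <- load_inputs(cfg)
    enr <- read_enriched(cfg)
    prop <- idiom_proportion_by_seniority(enr, inp$lexicon,
                                          cfg$analysis$idiom_s_cap)
    top <- top_idioms(enr, inp$lexicon)
    files <- c(stage_path(cfg, "idiom_proportion.csv"),
               stage_path(cfg, "top_idioms.csv"))
    readr::write_csv(prop, files[1])
    readr::write_csv(top, files[2])
  } else if (stage == "zipf") {
    inp <- load_inputs(cfg)
    fits <- list()
    for (what in c("words", "queries", "labels")) {
      toks <- switch(what,
        words = tokenize(inp$log$query),
        queries = normalize_text(inp$log$query),
        labels = as.character(inp$log$label_id))
      tab <- rank_frequency(toks[nzchar(toks)])
      p <- stage_path(cfg, paste0("zipf_", what, ".csv"))
      readr::write_csv(tab, p)
      files <- c(files, p)
      if (nrow(tab) >= 3) {
        fits[[what]] <- powerlaw_fit(tab, 1, min(100, nrow(tab)))
      }
    }
    jsonlite::write_json(fits, stage_path(cfg, "zipf_fits.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, stage_path(cfg, "zipf_fits.json"))
  } else if (stage == "report") {
    dst <- read_distance(cfg)
    cd <- curve_by_seniority(dst, "distance")
    cr <- curve_by_seniority(dst, "rank")
    summ <- list(
      n_records = nrow(dst),
      n_users = length(unique(dst$user)),
      n_labels = length(unique(dst$label_id)),
      max_seniority = max(dst$seniority),
      mean_distance_level1 = cd$mean[cd$level == 1],
      mean_rank_level1 = cr$mean[cr$level == 1],
      seed = cfg$seed, config_hash = config_hash(cfg)
    )
    files <- stage_path(cfg, "report.json")
    jsonlite::write_json(summ, files, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  write_provenance(cfg, stage, files)
  invisible(files)
}

read_enriched <- function(cfg) {
  p <- stage_path(cfg, "log_enriched.csv")
  if (!file.exists(p)) stop("missing input file: ", p,
                            " (run the enrich stage first)", call. = FALSE)
  readr::read_csv(p, col_types = readr::cols())
}

read_distance <- function(cfg) {
  p <- stage_path(cfg, "log_distance.csv")
  if (!file.exists(p)) stop("missing input file: ", p,
                            " (run the pareto stage first)", call. = FALSE)
  readr::read_csv(p, col_types = readr::cols())
}
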