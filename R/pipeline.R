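# Single entry point: configuration, end-to-end runs, CLI.

# FNV-1a hash of a string, hex; used to stamp outputs with their config
.config_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

.cfg_get <- function(cfg, field, default = NULL, required = FALSE) {
  if (!is.null(cfg[[field]])) return(cfg[[field]])
  if (required) stop("config field missing: ", field)
  default
}

.as_synth_config <- function(s) {
  if (inherits(s, "synthetic_config")) return(s)
  if (is.null(s$fs)) stop("config field missing: fs (sampling rate)")
  args <- s
  for (f in c("interictal_pac", "preictal_pac"))
    if (!is.null(args[[f]]) && !inherits(args[[f]], "pac_spec"))
      args[[f]] <- do.call(pac_spec, args[[f]])
  args$seizure_onsets <- as.numeric(unlist(args$seizure_onsets))
  do.call(synthetic_config, args)
}

#' Run the full pipeline from one configuration
#'
#' Stages: synthesize (or load) a recording, segment it, extract features,
#' classify, optionally sweep the SPH. Every stage's artifact lands in
#' `out_dir`, and a run manifest records the seed, package version and a
#' hash of the configuration so a rerun with the same config reproduces
#' every stochastic output bit for bit.
#'
#' @param config Nested list (or path to a JSON file) with fields:
#'   `seed`, `out_dir`, and per-stage sections `synth` (arguments of
#'   [synthetic_config()]) or `edf` (path), `segmentation` (arguments of
#'   [segmentation_config()]), `features` (arguments of
#'   [feature_config()]), `classifier` (arguments of [rf_config()]),
#'   optional `sweep` (`sph_values`).
#' @return The output directory, invisibly; artifacts: `recording.edf` (+
#'   seizure CSV), `windows.csv`, `features.csv`, `report.json`,
#'   `sweep.json` (when requested), `run_manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  seed <- .cfg_get(config, "seed", 1L)
  out_dir <- .cfg_get(config, "out_dir", required = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_core <- config
  cfg_core$out_dir <- NULL  # hash identifies the scientific config, not where it lands
  cfg_json <- jsonlite::toJSON(cfg_core, auto_unbox = TRUE, digits = NA, force = TRUE)
  hash <- .config_hash(as.character(cfg_json))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }

  rec <- stage("synth", {
    if (!is.null(config$edf)) read_edf(config$edf, config$channels)
    else {
      s <- .cfg_get(config, "synth", required = TRUE)
      s$seed <- .cfg_get(s, "seed", seed)
      r <- generate_recording(.as_synth_config(s))
      write_edf(r, file.path(out_dir, "recording.edf"))
      r
    }
  })

  seg_cfg <- do.call(segmentation_config, as.list(.cfg_get(config, "segmentation", list())))
  wins <- stage("segment", {
    ann <- merge_lead_seizures(rec$annotations, seg_cfg$cluster_gap_min)
    iv <- label_states(ncol(rec$signal) / rec$fs, ann, seg_cfg)
    w <- extract_windows(iv, seg_cfg, labels = c("interictal", "preictal"))
    w <- balance_windows(w, .subseed(seed, 11L))
    write.csv(w, file.path(out_dir, "windows.csv"), row.names = FALSE)
    w
  })

  fc_args <- as.list(.cfg_get(config, "features", list()))
  if (!is.null(fc_args$exclude_delta)) {
    ex <- isTRUE(fc_args$exclude_delta); fc_args$exclude_delta <- NULL
    fc_args$bands <- canonical_bands(exclude_delta = ex, fs = rec$fs)
  } else if (is.null(fc_args$bands)) fc_args$bands <- canonical_bands(fs = rec$fs)
  feat_cfg <- do.call(feature_config, fc_args)
  feats <- stage("features", {
    ft <- build_feature_table(rec, wins, feat_cfg)
    write.csv(ft, file.path(out_dir, "features.csv"), row.names = FALSE)
    ft
  })

  rf_cfg <- do.call(rf_config, as.list(.cfg_get(config, "classifier", list())))
  if (is.null(config$classifier$seed)) rf_cfg$seed <- .subseed(seed, 13L)
  report <- stage("classify", {
    rep <- suppressWarnings(train_eval(feats, rf_cfg))
    out <- list(config_hash = hash, seed = rf_cfg$seed,
                overall = as.list(rep$overall),
                per_channel = rep$per_channel, per_fold = rep$per_fold)
    jsonlite::write_json(out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    rep
  })

  if (!is.null(config$sweep)) {
    stage("sweep", {
      sw <- run_sweep(list(recording = rec), seg_cfg, feat_cfg, rf_cfg,
                      sph_values = as.numeric(unlist(config$sweep$sph_values)),
                      seed = .subseed(seed, 19L))
      jsonlite::write_json(
        list(config_hash = hash, accuracy = sw$accuracy, kruskal = sw$kruskal),
        file.path(out_dir, "sweep.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      sw
    })
  }

  manifest <- list(config_hash = hash, seed = seed,
                   package = "pacpredict",
                   version = as.character(utils::packageVersion("pacpredict")),
                   r_version = R.version.string,
                   config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

.cli_opts <- function(args) {
  opts <- list(); pos <- character(0); i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      vals <- character(0)
      while (i < length(args) && !startsWith(args[i + 1], "--")) {
        vals <- c(vals, args[i + 1]); i <- i + 1
      }
      opts[[key]] <- if (length(vals)) vals else TRUE
    } else pos <- c(pos, a)
    i <- i + 1
  }
  list(opts = opts, pos = pos)
}

#' Command-line interface
#'
#' Subcommands: `synth --config cfg.json --out rec.edf`;
#' `inspect rec.edf`; `segment rec.edf --sph 5 --out windows.csv`;
#' `features rec.edf --windows windows.csv --set both --out features.csv`;
#' `classify features.csv --k 10 --seed 7 --out report.json`;
#' `sweep --config cfg.json --out sweep.json`; `run --config cfg.json`.
#'
#' @param args Character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status, invisibly.
#' @export
pac_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: pacpredict <synth|inspect|segment|features|classify|sweep|run> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  p <- .cli_opts(args[-1])
  o <- p$opts
  num1 <- function(x, d) if (is.null(x)) d else as.numeric(x[1])
  switch(cmd,
    synth = {
      cfg <- jsonlite::read_json(o$config[1], simplifyVector = TRUE)
      rec <- generate_recording(.as_synth_config(cfg))
      write_edf(rec, o$out[1])
      cat(sprintf("wrote %s (%d channel(s), %.0f s)\n", o$out[1],
                  nrow(rec$signal), ncol(rec$signal) / rec$fs))
    },
    inspect = {
      rec <- read_edf(p$pos[1])
      print(rec)
      cat("channels:", paste(rec$channel_names, collapse = ", "), "\n")
      if (nrow(rec$annotations))
        for (i in seq_len(nrow(rec$annotations)))
          cat(sprintf("seizure %d: %g-%g s\n", i, rec$annotations$onset_s[i],
                      rec$annotations$offset_s[i]))
    },
    segment = {
      rec <- read_edf(p$pos[1])
      sc <- segmentation_config(sph_min = num1(o$sph, 5))
      ann <- merge_lead_seizures(rec$annotations, sc$cluster_gap_min)
      iv <- label_states(ncol(rec$signal) / rec$fs, ann, sc)
      w <- extract_windows(iv, sc)
      write.csv(w, o$out[1], row.names = FALSE)
      cat(sprintf("wrote %s (%d windows)\n", o$out[1], nrow(w)))
    },
    features = {
      rec <- read_edf(p$pos[1])
      w <- read.csv(o$windows[1])
      fset <- if (is.null(o$set)) "both" else o$set[1]
      fc <- feature_config(bands = canonical_bands(fs = rec$fs), feature_set = fset)
      ft <- build_feature_table(rec, w, fc)
      write.csv(ft, o$out[1], row.names = FALSE)
      cat(sprintf("wrote %s (%d rows)\n", o$out[1], nrow(ft)))
    },
    classify = {
      ft <- read.csv(p$pos[1])
      rc <- rf_config(k = as.integer(num1(o$k, 10)), seed = as.integer(num1(o$seed, 1)))
      rep <- suppressWarnings(train_eval(ft, rc))
      jsonlite::write_json(list(overall = as.list(rep$overall),
                                per_channel = rep$per_channel),
                           o$out[1], auto_unbox = TRUE, digits = NA, dataframe = "rows")
      print(rep)
    },
    sweep = {
      cfg <- jsonlite::read_json(o$config[1], simplifyVector = TRUE)
      recs <- lapply(unlist(cfg$recordings), read_edf)
      sw <- run_sweep(recs, sph_values = as.numeric(unlist(cfg$sph_values)),
                      seed = as.integer(.cfg_get(cfg, "seed", 1L)))
      jsonlite::write_json(list(accuracy = sw$accuracy, kruskal = sw$kruskal),
                           o$out[1], auto_unbox = TRUE, digits = NA, dataframe = "rows")
      print(sw)
    },
    run = {
      out <- run_pipeline(o$config[1])
      cat("run complete:", out, "\n")
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}
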