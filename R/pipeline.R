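#' Per-contribution rhythm tables
#'
#' Computes, for every contribution, the stage tables the rhythm analysis
#' emits: the IOI table (one row per successive onset pair, with the
#' ceiling-filter mask), the ratio table (with on/off/outside band labels),
#' the whole-contribution isochrony table, the chunked call-rate table with
#' the song-type median split, and pooled tempo peaks per song type.
#'
#' @param contributions List of `"contribution"` objects.
#' @param max_ioi IOI ceiling in seconds.
#' @param boundaries An [isochrony_boundaries()].
#' @param window_s Call-rate window in seconds.
#' @param chunk_isochrony Also compute isochrony per call-rate chunk
#'   (default `TRUE`).
#' @return A list of data frames: `ioi_table`, `ratio_table`,
#'   `isochrony_table`, `callrate_table`, `chunk_isochrony_table`,
#'   `tempo_peaks`.
#' @export
rhythm_tables <- function(contributions, max_ioi = 5.0,
                          boundaries = isochrony_boundaries(),
                          window_s = 10.0, chunk_isochrony = TRUE) {
  ioi_rows <- list(); ratio_rows <- list(); iso_rows <- list()
  rate_rows <- list(); chunk_iso_rows <- list()
  pooled <- list()
  for (ct in contributions) {
    id <- list(song_id = ct$song_id, individual_id = ct$individual_id,
               sex = ct$sex, song_type = ct$song_type, context = ct$context)
    if (nrow(ct$notes) < 2) next
    iois <- extract_iois(ct, max_ioi)
    ioi_rows[[length(ioi_rows) + 1L]] <- data.frame(
      id, k = seq_along(iois$values), t_k = iois$values, kept = iois$kept,
      stringsAsFactors = FALSE)
    pooled[[ct$song_type]] <- c(pooled[[ct$song_type]],
                                iois$values[iois$kept])
    ratios <- compute_ratios(iois)
    if (length(ratios$values)) {
      b <- boundaries
      band <- ifelse(ratios$values >= b$inner_low &
                       ratios$values <= b$inner_high, "on",
                     ifelse((ratios$values >= b$outer_low &
                               ratios$values < b$inner_low) |
                              (ratios$values > b$inner_high &
                                 ratios$values <= b$outer_high),
                            "off", "outside"))
      ratio_rows[[length(ratio_rows) + 1L]] <- data.frame(
        id, k = ratios$pair_index, r_k = ratios$values, band = band,
        stringsAsFactors = FALSE)
    }
    cnt <- classify_ratios(ratios, boundaries, window = "contribution")
    rate <- isochrony_rate(cnt)
    iso_rows[[length(iso_rows) + 1L]] <- data.frame(
      id, on_count = cnt$on_count, off_count = cnt$off_count,
      total_ratios = cnt$total_ratios, isochrony_rate = rate$value,
      defined = rate$defined, stringsAsFactors = FALSE)
    cr <- call_rate(ct, window_s)
    if (nrow(cr$chunks)) {
      rate_rows[[length(rate_rows) + 1L]] <- data.frame(
        id, cr$chunks, stringsAsFactors = FALSE)
      if (chunk_isochrony) {
        for (w in seq_len(nrow(cr$chunks))) {
          sel <- ct$notes$onset >= cr$chunks$start[w] &
            ct$notes$onset < cr$chunks$end[w]
          if (sum(sel) < 3) next
          wiois <- suppressWarnings(extract_iois(ct$notes$onset[sel], max_ioi))
          wcnt <- classify_ratios(compute_ratios(wiois), boundaries, window = w)
          wrate <- isochrony_rate(wcnt)
          chunk_iso_rows[[length(chunk_iso_rows) + 1L]] <- data.frame(
            id, chunk = w, on_count = wcnt$on_count,
            off_count = wcnt$off_count, isochrony_rate = wrate$value,
            defined = wrate$defined, stringsAsFactors = FALSE)
        }
      }
    }
  }
  peaks <- list()
  for (st in names(pooled)) {
    if (length(pooled[[st]]) < 2) next
    tp <- suppressWarnings(density_peaks(pooled[[st]], max_ioi = max_ioi))
    if (nrow(tp$peaks)) {
      peaks[[st]] <- data.frame(song_type = st, tp$peaks,
                                stringsAsFactors = FALSE)
    }
  }
  bind <- function(rows) if (length(rows)) {
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  } else NULL
  rate_tab <- bind(rate_rows)
  if (!is.null(rate_tab)) rate_tab <- median_split(rate_tab)
  list(ioi_table = bind(ioi_rows), ratio_table = bind(ratio_rows),
       isochrony_table = bind(iso_rows), callrate_table = rate_tab,
       chunk_isochrony_table = bind(chunk_iso_rows),
       tempo_peaks = bind(unname(peaks)))
}

#' Pipeline configuration
#'
#' Assembles and validates every stage parameter. `input` is either a
#' directory of TextGrids, a single onsets CSV, or `NULL` when `simulate`
#' is given.
#'
#' @param input Path to a TextGrid directory or onsets CSV.
#' @param simulate Optional list of arguments to [generate_dataset()]
#'   (excluding `out_dir` and `seed`); the simulated fixtures are written
#'   under the output directory.
#' @param max_ioi,boundaries,window_s Rhythm parameters.
#' @param granger A [granger_spec()].
#' @param bin_s Binarization width in seconds.
#' @param chunks A [chunk_spec()].
#' @param n_permutations Permutation draws per scheme.
#' @param wild_only Restrict causality and synchrony stages to wild songs.
#' @param seed Seed for simulation and permutation.
#' @param out_dir Output directory.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL, max_ioi = 5.0,
                            boundaries = isochrony_boundaries(),
                            window_s = 10.0, granger = granger_spec(),
                            bin_s = 0.010, chunks = chunk_spec(),
                            n_permutations = 1000, wild_only = TRUE,
                            seed = 1, out_dir = "duetrhythm_out") {
  if (is.null(input) && is.null(simulate)) {
    stop("either `input` or `simulate` must be given", call. = FALSE)
  }
  stopifnot(max_ioi > 0, window_s > 0, bin_s > 0, n_permutations >= 1,
            inherits(boundaries, "isochrony_boundaries"),
            inherits(granger, "granger_spec"), inherits(chunks, "chunk_spec"))
  structure(list(input = input, simulate = simulate, max_ioi = max_ioi,
                 boundaries = boundaries, window_s = window_s,
                 granger = granger, bin_s = bin_s, chunks = chunks,
                 n_permutations = as.integer(n_permutations),
                 wild_only = wild_only, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML keys mirror the [pipeline_config()] arguments; `boundaries` is
#' a 4-vector, `granger` and `chunks` are nested maps with the respective
#' constructor arguments.
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$boundaries)) {
    args$boundaries <- do.call(isochrony_boundaries,
                               as.list(as.numeric(y$boundaries)))
  }
  if (!is.null(y$granger)) args$granger <- do.call(granger_spec, y$granger)
  if (!is.null(y$chunks)) args$chunks <- do.call(chunk_spec, y$chunks)
  do.call(pipeline_config, args)
}

load_input <- function(config) {
  inp <- config$input
  if (dir.exists(inp)) {
    paths <- list.files(inp, pattern = "\\.[Tt]ext[Gg]rid$",
                        full.names = TRUE)
    if (!length(paths)) stop("no TextGrid files under ", inp, call. = FALSE)
    unlist(lapply(paths, read_textgrid), recursive = FALSE)
  } else if (file.exists(inp)) {
    read_onsets_csv(inp)
  } else {
    stop("input '", inp, "' not found", call. = FALSE)
  }
}

#' Run the full analysis pipeline
#'
#' Executes annotation input (or simulation), the rhythm statistics, the
#' Granger-causality census, and the synchrony/permutation stage, writing
#' every stage table as CSV plus a joined per-contribution
#' `analysis_table.csv` (isochrony rate, mean call rate, overlap metrics,
#' sex, song type — the row set a downstream mixed model consumes) and a
#' `run_log.txt` recording parameters and seed. Any stage failure aborts
#' with a stage-named error.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @return Invisibly, a list with every stage result and the table paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  contributions <- stage("input", {
    if (!is.null(config$simulate)) {
      fix_dir <- file.path(config$out_dir, "fixtures")
      args <- config$simulate
      args$out_dir <- fix_dir
      args$seed <- config$seed
      gen <- do.call(generate_dataset, args)
      unlist(lapply(gen$songs, `[[`, "contributions"), recursive = FALSE)
    } else {
      load_input(config)
    }
  })
  songs <- stage("input", collect_songs(contributions))

  tabs <- stage("rhythm_core",
                rhythm_tables(contributions, config$max_ioi,
                              config$boundaries, config$window_s))

  census <- stage("interaction", {
    duets <- Filter(is_duet, songs)
    if (length(duets)) {
      causality_census(songs, config$granger, config$bin_s,
                       wild_only = config$wild_only)
    } else NULL
  })

  synch <- stage("synchrony", {
    duets <- Filter(is_duet, songs)
    if (config$wild_only) {
      duets <- Filter(function(s) s$contributions[[1]]$context == "wild",
                      duets)
    }
    if (!length(duets)) NULL else {
      real <- lapply(duets, function(s)
        overlap_metrics(duet_female(s), duet_male(s)))
      real_tab <- do.call(rbind, lapply(seq_along(duets), function(i) {
        om <- real[[i]]
        data.frame(song_id = duets[[i]]$song_id, label = "REAL",
                   overlap_s = om$overlap_s, rate_female = om$rate_female,
                   rate_male = om$rate_male,
                   normalized_overlap = om$normalized_overlap,
                   stringsAsFactors = FALSE)
      }))
      chks <- chunk_songs(songs, config$chunks, wild_only = config$wild_only)
      nulls <- list()
      for (mode in c("real_couples", "random_couples")) {
        nd <- tryCatch(
          permute_duets(chks, permutation_scheme(mode,
                                                 config$n_permutations,
                                                 seed = sub_seed(config$seed,
                                                                 match(mode, c("real_couples", "random_couples"))))),
          error = function(e) NULL)   # e.g. single-group data: no random pairs
        if (!is.null(nd)) nulls[[mode]] <- nd
      }
      tests <- lapply(nulls, function(nd)
        chance_test(vapply(real, `[[`, 0, "normalized_overlap"), nd))
      list(real = real_tab, nulls = nulls, tests = tests)
    }
  })

  paths <- character(0)
  emit <- function(tab, name) {
    if (is.null(tab)) return(invisible(NULL))
    p <- file.path(config$out_dir, name)
    write.csv(tab, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  emit(tabs$ioi_table, "ioi_table.csv")
  emit(tabs$ratio_table, "ratio_table.csv")
  emit(tabs$isochrony_table, "isochrony_table.csv")
  emit(tabs$callrate_table, "callrate_table.csv")
  emit(tabs$chunk_isochrony_table, "chunk_isochrony_table.csv")
  emit(tabs$tempo_peaks, "tempo_peaks.csv")
  if (!is.null(census)) {
    emit(census$table, "granger_table.csv")
    emit(data.frame(metric = c(paste0("prop_significant_",
                                      names(census$prop_significant)),
                               paste0("prop_", names(census$prop_class))),
                    value = c(census$prop_significant, census$prop_class)),
         "census_summary.csv")
  }
  if (!is.null(synch)) {
    sim_tabs <- lapply(names(synch$nulls), function(mode)
      data.frame(song_id = NA, label = paste0("SIM_", mode),
                 overlap_s = NA, rate_female = NA, rate_male = NA,
                 normalized_overlap =
                   synch$nulls[[mode]]$draws$normalized_overlap,
                 stringsAsFactors = FALSE))
    emit(do.call(rbind, c(list(synch$real), sim_tabs)), "overlap_table.csv")
  }

  joined <- stage("join", {
    iso <- tabs$isochrony_table
    cr <- tabs$callrate_table
    if (!is.null(cr)) {
      mean_rate <- stats::aggregate(rate ~ song_id + individual_id, cr, mean)
      names(mean_rate)[3] <- "mean_call_rate"
      iso <- merge(iso, mean_rate, by = c("song_id", "individual_id"),
                   all.x = TRUE)
    }
    if (!is.null(synch)) {
      ov <- synch$real
      long <- rbind(
        data.frame(song_id = ov$song_id, sex = "female",
                   overlap_rate = ov$rate_female,
                   normalized_overlap = ov$normalized_overlap),
        data.frame(song_id = ov$song_id, sex = "male",
                   overlap_rate = ov$rate_male,
                   normalized_overlap = ov$normalized_overlap))
      iso <- merge(iso, long, by = c("song_id", "sex"), all.x = TRUE)
    }
    iso[order(iso$song_id, iso$individual_id), , drop = FALSE]
  })
  emit(joined, "analysis_table.csv")

  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(c(
    paste0("duetrhythm ", as.character(utils::packageVersion("duetrhythm"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", config$seed),
    paste0("max_ioi: ", config$max_ioi),
    paste0("boundaries: ", paste(unlist(config$boundaries), collapse = " ")),
    paste0("call_rate_window_s: ", config$window_s),
    paste0("granger: lag ", config$granger$lag_order, ", alpha ",
           config$granger$alpha,
           if (!is.null(config$granger$max_len))
             paste0(", max_len ", config$granger$max_len) else ""),
    paste0("bin_s: ", config$bin_s),
    paste0("chunk_s: ", config$chunks$chunk_s, " (min_keep ",
           config$chunks$min_keep_s, ")"),
    paste0("n_permutations: ", config$n_permutations),
    paste0("wild_only: ", config$wild_only),
    paste0("n_contributions: ", length(contributions)),
    paste0("tables: ", paste(basename(paths), collapse = ", "))),
    log_path)

  invisible(list(contributions = contributions, songs = songs,
                 tables = tabs, census = census, synchrony = synch,
                 analysis_table = joined, paths = c(paths, log_path),
                 config = config))
}
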