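# End-to-end orchestration: simulate -> analyse -> compare -> report.

#' Default demo configuration for [run_pipeline()]
#'
#' A fully synthetic two-genotype cohort at the scale of the modelled
#' experiments: home-cage photometry of 10 min per animal (n = 7 WT, 5 AD),
#' dual-site arena recordings with 20 exploration bouts per phase and
#' coupling 0.8 (encoding) vs 0 (retrieval), sIPSC recordings with one
#' 20-s light epoch per 60-s cycle (n = 8 WT, 12 AD cells), the 16-step
#' F-I ladder, and retrograde/anterograde tracing brains.  Genotype
#' overrides encode the modelled phenotypes: doubled DG event rate,
#' increased membrane resistance and rheobase, and doubled hilar process
#' density in the AD group.
#'
#' @param seed integer global seed.
#' @return a nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    n_animals = c(WT = 7L, AD = 5L),
    photometry = list(duration_s = 600),
    coupling = list(n_bouts = 20, rho_encoding = 0.8, rho_retrieval = 0,
                    window = c(-2, 4)),
    behavior = list(p_novel = c(WT = 0.7, AD = 0.5), n_bouts = 20),
    ephys = list(n_cells = c(WT = 8L, AD = 12L), sipsc_duration_s = 60,
                 genotype = list(WT = list(R_Mohm = 150, rheobase_pA = 110),
                                 AD = list(R_Mohm = 200, rheobase_pA = 150))),
    tracing = list(n_retro = c(WT = 3L, AD = 3L),
                   n_antero = c(WT = 3L, AD = 3L),
                   n_processes = c(WT = 20L, AD = 40L))
  )
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes simulate -> photometry -> peri-event coupling -> behavior ->
#' ephys -> tracing -> group comparisons, deterministically for a given
#' config + seed, and optionally writes the report as CSV tables (plus
#' simple PDF figures on request).  A failure in any stage halts with a
#' stage-attributed error; tables of completed stages are still returned
#' via the error's `partial` attribute when writing.
#'
#' @param config configuration list from [default_config()], or a path to
#'   a JSON/YAML config file.
#' @param out_dir optional report directory (created if needed).
#' @param figures also write PDF figures (default FALSE; PDFs are not
#'   byte-stable across runs, tables are).
#' @return an `AnalysisReport`: named list of data.frames
#'   (`photometry_summary`, `coupling`, `behavior_scores`,
#'   `ephys_cells`, `fi_anova`, `tracing_summary`, `comparisons`,
#'   `exclusions`) plus `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         figures = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config), !is.null(config$seed))
  report <- list(config = config)
  exclusions <- data.frame(stage = character(0), unit = character(0),
                           reason = character(0))
  comparisons <- list()
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  ## -- photometry: home-cage activity per animal -------------------------
  st <- stage("photometry", function() pipeline_photometry(config))
  report$photometry_summary <- st$summary
  comparisons$photometry <- st$comparisons

  ## -- peri-event coupling (encoding vs retrieval) -----------------------
  st <- stage("perievent", function() pipeline_coupling(config))
  report$coupling <- st$table
  comparisons$coupling <- st$comparisons

  ## -- behavior: recognition scores --------------------------------------
  st <- stage("behavior", function() pipeline_behavior(config))
  report$behavior_scores <- st$scores
  comparisons$behavior <- st$comparisons
  exclusions <- rbind(exclusions, st$exclusions)

  ## -- ephys -------------------------------------------------------------
  st <- stage("ephys", function() pipeline_ephys(config))
  report$ephys_cells <- st$cells
  report$fi_anova <- st$fi_anova
  comparisons$ephys <- st$comparisons
  exclusions <- rbind(exclusions, st$exclusions)

  ## -- tracing -----------------------------------------------------------
  st <- stage("tracing", function() pipeline_tracing(config))
  report$tracing_summary <- st$summary
  comparisons$tracing <- st$comparisons

  report$comparisons <- do.call(rbind, c(comparisons,
                                         make.row.names = FALSE))
  report$comparisons$n_tests <- nrow(report$comparisons)
  report$exclusions <- exclusions

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(report), "config"))
      utils::write.csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(config, file.path(out_dir, "config_snapshot.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (figures) pipeline_figures(config, out_dir)
  }
  class(report) <- "septodg_report"
  report
}

# fields stored as JSON/YAML objects (to keep names) but used as vectors
.named_fields <- list(c("n_animals"), c("behavior", "p_novel"),
                      c("ephys", "n_cells"), c("tracing", "n_retro"),
                      c("tracing", "n_antero"), c("tracing", "n_processes"))

#' Read / write a pipeline configuration file
#'
#' JSON (default) or YAML.  Named group parameters (e.g. animals per
#' genotype) are stored as objects so group names survive the round trip.
#'
#' @param path config file path (`.json`, `.yaml`/`.yml`).
#' @param config a configuration list (see [default_config()]).
#' @return `read_config()`: the configuration list; `write_config()`:
#'   `path`, invisibly.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  for (fld in .named_fields) {
    v <- tryCatch(cfg[[fld]], error = function(e) NULL)
    if (is.list(v) && length(v)) cfg[[fld]] <- unlist(v)
  }
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  for (fld in .named_fields) {
    v <- tryCatch(config[[fld]], error = function(e) NULL)
    if (is.atomic(v) && !is.null(names(v))) config[[fld]] <- as.list(v)
  }
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::write_yaml(config, path)
  } else jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
  invisible(path)
}

base_cfg <- function(config, ...) {
  sim_config(seed = config$seed,
             n_animals_per_group = config$n_animals, ...)
}

pipeline_photometry <- function(config) {
  cfg <- base_cfg(config,
                  photometry = list(duration_s = config$photometry$duration_s))
  rows <- list()
  for (g in names(config$n_animals)) {
    for (a in seq_len(config$n_animals[[g]])) {
      for (site in c("DG", "MS")) {
        sim <- simulate_photometry_session(cfg, g, site,
                                           animal = paste0(g, a))
        res <- analyze_photometry_session(sim$session)
        rows[[length(rows) + 1]] <- data.frame(
          genotype = g, animal = paste0(g, a), site = site,
          rate_per_min = res$activity$rate_per_min,
          auc = res$activity$auc,
          suprathreshold_frac = res$activity$suprathreshold_frac,
          true_rate = sim$truth$rate_per_min)
      }
    }
  }
  summary <- do.call(rbind, rows)
  comp <- do.call(rbind, lapply(c("DG", "MS"), function(site) {
    sub <- summary[summary$site == site, ]
    rbind(
      run_comparison(data.frame(value = sub$rate_per_min,
                                group = sub$genotype),
                     comparison_spec("unpaired_t", unit = "animal",
                                     measure = paste0(site, "_event_rate"))),
      run_comparison(data.frame(value = sub$auc, group = sub$genotype),
                     comparison_spec("unpaired_t", unit = "animal",
                                     measure = paste0(site, "_auc"))))
  }))
  list(summary = summary, comparisons = comp)
}

pipeline_coupling <- function(config) {
  cc <- config$coupling
  cfg <- base_cfg(config,
                  behavior = list(n_bouts = cc$n_bouts, duration_s = 300))
  rows <- list(); comp <- list()
  for (phase in c("familiarization", "test")) {
    rho <- if (phase == "familiarization") cc$rho_encoding else cc$rho_retrieval
    track <- simulate_behavior_track(cfg, phase,
                                     seed = child_seed(cfg$seed,
                                                       paste0("cptrack/", phase)))
    pair <- simulate_paired_sessions(cfg, track, rho = rho,
                                     seed = child_seed(cfg$seed,
                                                       paste0("cppair/", phase)))
    resp <- lapply(pair[c("dg", "ms")], function(s) {
      d <- analyze_photometry_session(s$session, motion_correct = TRUE)$dff
      al <- align_timebases(d, track)
      pem <- build_perievent(d, al$bouts, window = cc$window)
      list(resp = bout_response(pem), pem = pem)
    })
    n <- min(length(resp$dg$resp), length(resp$ms$resp))
    cp <- coupling(resp$dg$resp[seq_len(n)], resp$ms$resp[seq_len(n)])
    rows[[phase]] <- data.frame(phase = phase, rho_true = rho, r = cp$r,
                                p = cp$p, n_bouts = cp$n,
                                sig = isTRUE(cp$sig))
    comp[[phase]] <- run_comparison(
      data.frame(x = resp$dg$resp[seq_len(n)], y = resp$ms$resp[seq_len(n)]),
      comparison_spec("pearson", unit = "bout",
                      measure = paste0("coupling_", phase)))
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       comparisons = do.call(rbind, comp))
}

pipeline_behavior <- function(config) {
  bc <- config$behavior
  cfg <- base_cfg(config, behavior = list(n_bouts = bc$n_bouts))
  rows <- list(); excl <- list()
  for (g in names(config$n_animals)) {
    p_nov <- bc$p_novel[[g]]
    for (a in seq_len(config$n_animals[[g]])) {
      id <- paste0(g, a)
      track <- simulate_behavior_track(
        cfg, "test", object_probs = c(A = 1 - p_nov, B = p_nov),
        seed = child_seed(cfg$seed, paste0("behav/", id)))
      bouts <- detect_bouts(track)
      sc <- recognition_score(bouts, novel_object = "B")
      if (sc$excluded) {
        excl[[id]] <- data.frame(stage = "behavior", unit = id,
                                 reason = "zero total exploration")
        next
      }
      tb <- tapply(bouts$duration, bouts$object, sum)
      rows[[id]] <- data.frame(
        genotype = g, animal = id, score = sc$score,
        latency = sc$latency_to_first_bout,
        t_A = if ("A" %in% names(tb)) unname(tb[["A"]]) else 0,
        t_B = if ("B" %in% names(tb)) unname(tb[["B"]]) else 0)
    }
  }
  scores <- do.call(rbind, c(rows, make.row.names = FALSE))
  comp <- group_behavior_compare(scores)
  list(scores = scores, comparisons = comp,
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(stage = character(0), unit = character(0),
                    reason = character(0)))
}

pipeline_ephys <- function(config) {
  ec <- config$ephys
  cells <- list(); tables <- list(); fi_tabs <- list()
  groups <- character(0); excl <- list()
  for (g in names(ec$n_cells)) {
    gpar <- ec$genotype[[g]] %||% list()
    for (ci in seq_len(ec$n_cells[[g]])) {
      id <- paste0(g, "_cell", ci)
      # per-cell biological variability (~10% CV) around the genotype means
      set.seed(child_seed(config$seed, paste0("cellvar/", id)))
      cpar <- gpar
      cpar$R_Mohm <- (gpar$R_Mohm %||% 150) * exp(stats::rnorm(1, 0, 0.1))
      cpar$tau_ms <- (gpar$tau_ms %||% 20) * exp(stats::rnorm(1, 0, 0.1))
      cfg <- base_cfg(config, ephys = cpar)
      lp <- light_protocol(ec$sipsc_duration_s)
      sim <- simulate_sipsc_trace(cfg, ec$sipsc_duration_s, light = lp,
                                  cell = id)
      qc <- qc_access_resistance(sim$sweeps$ra_checkpoints)
      if (identical(qc$pass, FALSE)) {
        excl[[id]] <- data.frame(stage = "ephys", unit = id,
                                 reason = qc$reason)
        next
      }
      tb <- detect_sipscs(sim$sweeps$traces[[1]], fs = cfg$ephys$fs)
      stp <- simulate_current_steps(cfg, cell = id)
      ip <- intrinsic_properties(stp$sweeps)
      tables[[id]] <- tb; groups <- c(groups, g)
      fi_tabs[[id]] <- ip$fi
      cells[[id]] <- data.frame(
        genotype = g, cell = id,
        sipsc_freq = attr(tb, "frequency_hz"),
        sipsc_amp = if (nrow(tb)) mean(tb$amplitude) else NA,
        rin_Mohm = ip$rin_Mohm, tau_ms = ip$tau_ms,
        capacitance_pF = ip$capacitance_pF, rmp_mV = ip$rmp_mV,
        rheobase_pA = ip$rheobase_pA)
    }
  }
  cells_df <- do.call(rbind, c(cells, make.row.names = FALSE))
  gs <- sipsc_group_stats(tables, groups)
  opto <- opto_epoch_compare(tables, light_protocol(ec$sipsc_duration_s))
  rin_cmp <- run_comparison(data.frame(value = cells_df$rin_Mohm,
                                       group = cells_df$genotype),
                            comparison_spec("unpaired_t", unit = "cell",
                                            measure = "input_resistance_Mohm"))
  fi_anova <- fi_group_compare(fi_tabs, groups)
  comp <- rbind(gs$comparisons, opto$comparisons, rin_cmp)
  list(cells = cells_df, fi_anova = fi_anova, comparisons = comp,
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(stage = character(0), unit = character(0),
                    reason = character(0)))
}

pipeline_tracing <- function(config) {
  tc <- config$tracing
  rows <- list()
  for (g in names(tc$n_retro)) {
    for (b in seq_len(tc$n_retro[[g]])) {
      cfg <- base_cfg(config)
      sim <- simulate_tracing_volume(cfg, "retrograde_sections",
                                     seed = child_seed(cfg$seed,
                                                       paste0("retro/", g, b)))
      cr <- connectivity_ratio(lapply(sim$data$sections, `[[`, "mcherry"),
                               sim$rois[names(sim$rois) != "starter_DG"],
                               sim$data$starter_image,
                               sim$rois$starter_DG,
                               pixel_um = sim$pixel_um)
      cf <- colocalization_fraction(lapply(sim$data$sections, `[[`, "mcherry"),
                                    lapply(sim$data$sections, `[[`, "gaba"),
                                    roi = sim$rois$MS,
                                    pixel_um = sim$pixel_um)
      rows[[paste0("r", g, b)]] <- data.frame(
        genotype = g, brain = paste0(g, b), assay = "retrograde",
        ms_connectivity_ratio =
          cr$ranking$ratio[cr$ranking$region == "MS"],
        coloc_fraction = cf$fraction,
        normalized_density = NA_real_)
    }
    for (b in seq_len(tc$n_antero[[g]])) {
      cfg <- base_cfg(config,
                      imaging = list(n_processes = tc$n_processes[[g]]))
      sim <- simulate_tracing_volume(cfg, "anterograde_volume",
                                     seed = child_seed(cfg$seed,
                                                       paste0("antero/", g, b)))
      cc <- count_cells(sim$data$ms_image, sim$rois$ms)
      pr <- reconstruct_processes_3d(sim$data$volume, sim$rois$hilus,
                                     cell_density = cc$density)
      rows[[paste0("a", g, b)]] <- data.frame(
        genotype = g, brain = paste0(g, b, "a"), assay = "anterograde",
        ms_connectivity_ratio = NA_real_, coloc_fraction = NA_real_,
        normalized_density = pr$normalized_density)
    }
  }
  summary <- do.call(rbind, c(rows, make.row.names = FALSE))
  retro <- summary[summary$assay == "retrograde", ]
  antero <- summary[summary$assay == "anterograde", ]
  comp <- rbind(
    run_comparison(data.frame(value = retro$ms_connectivity_ratio,
                              group = retro$genotype),
                   comparison_spec("unpaired_t", unit = "animal",
                                   measure = "MS_connectivity_ratio")),
    run_comparison(data.frame(value = retro$coloc_fraction,
                              group = retro$genotype),
                   comparison_spec("unpaired_t", unit = "animal",
                                   measure = "coloc_fraction")),
    run_comparison(data.frame(value = antero$normalized_density,
                              group = antero$genotype),
                   comparison_spec("unpaired_t", unit = "animal",
                                   measure = "normalized_projection_density")))
  list(summary = summary, comparisons = comp)
}

# simple base-graphics figures; optional because PDFs embed timestamps
pipeline_figures <- function(config, out_dir) {
  cfg <- base_cfg(config)
  grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 7, height = 5)
  on.exit(grDevices::dev.off())
  track <- simulate_behavior_track(cfg, "familiarization")
  pair <- simulate_paired_sessions(cfg, track, rho = 0.8)
  d <- analyze_photometry_session(pair$dg$session)$dff
  al <- align_timebases(d, track)
  pem <- build_perievent(d, al$bouts)
  graphics::image(pem$t, seq_len(nrow(pem$scaled)), t(pem$scaled),
                  xlab = "time from bout onset (s)", ylab = "bout",
                  main = "Scaled peri-event heat map (DG)")
  graphics::plot(pem$t, colMeans(pem$mat), type = "l",
                 xlab = "time from bout onset (s)", ylab = "dF/F",
                 main = "Averaged bout-locked activity")
  graphics::abline(v = 0, lty = 2)
  sim <- simulate_sipsc_trace(cfg, 30)
  tb <- detect_sipscs(sim$sweeps$traces[[1]])
  if (nrow(tb) > 1)
    graphics::plot(stats::ecdf(tb$amplitude), main = "sIPSC amplitude CDF",
                   xlab = "amplitude (pA)")
  stp <- simulate_current_steps(cfg)
  ip <- intrinsic_properties(stp$sweeps)
  graphics::plot(ip$fi$current_pA, ip$fi$spikes, type = "b",
                 xlab = "injected current (pA)", ylab = "spikes / 500 ms",
                 main = "F-I curve")
  invisible(NULL)
}

#' @export
print.septodg_report <- function(x, ...) {
  cat("<septodg_report>\n")
  for (nm in setdiff(names(x), c("config"))) {
    d <- x[[nm]]
    if (is.data.frame(d))
      cat(sprintf("  %s: %d rows x %d cols\n", nm, nrow(d), ncol(d)))
  }
  invisible(x)
}
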