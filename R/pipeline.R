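## End-to-end orchestration: a serializable run configuration, staged
## execution with versioned artifacts and manifests, and a summary report
## assembling the four result panels (network dichotomy, staircase traces,
## ERP differences, time-frequency statistics).

#' Build a full pipeline run configuration
#'
#' Stage-specific parameter blocks plus a single global seed from which
#' every stage derives a named substream. All values are JSON-serializable.
#' The defaults give a desk-scale run: reduced repetition counts and a
#' posterior-midline EEG montage; the statistical machinery is identical
#' at every scale.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory for artifacts.
#' @param stimuli,networks,quest,eeg,erp,tf Named lists overriding the
#'   per-stage defaults (partial overrides are merged).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = "visreason_run",
                       stimuli = list(), networks = list(), quest = list(),
                       eeg = list(), erp = list(), tf = list()) {
  merge <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  structure(list(
    seed = as.integer(seed), out_dir = out_dir,
    stimuli = merge(list(n = 1000L, n_export_png = 16L, scale = 1L), stimuli),
    networks = merge(list(n_reps = 3L, n_train = 1000L, n_val = 1000L,
                          n_test = 1000L, learning_rate = 1e-3,
                          epochs_cnn = 70L, epochs_siamese = 150L), networks),
    quest = merge(list(n_blocks = 16L, trials_per_block = 70L,
                       rho_threshold = 8, theta_threshold = 3), quest),
    eeg = merge(list(n_subjects = 14L, trials_per_condition = 100L,
                     montage_labels = c("Oz", "O1", "O2", "POz", "PO3", "PO4",
                                        "Pz", "CPz", "Cz", "FCz", "Fz"),
                     sfreq = 256, t_end = 2.0), eeg),
    erp = merge(list(q = 0.05), erp),
    tf = merge(list(n_freqs = 20L, f_min = 4, f_max = 40, decim = 8L,
                    t_threshold = 3.5, n_permutations = 500L, alpha = 0.05),
               tf)),
    class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(dir, stage, files, config, seed) {
  paths <- file.path(dir, files)
  jsonlite::write_json(list(
    stage = stage, seed = seed, config_hash = config_hash(config),
    files = data.frame(file = files,
                       md5 = unname(tools::md5sum(paths)))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

#' Run pipeline stages and write versioned artifacts
#'
#' Executes the requested stages in dependency order. Each stage writes
#' its artifacts plus a `manifest.json` embedding the config hash and the
#' stage seed, so reruns with an identical configuration produce identical
#' manifests. The `report` stage assembles all previously computed results
#' into a markdown summary with figures.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stages to run, in
#'   `c("shapes", "stimgen", "train-nets", "behavior", "synth-eeg", "erp",
#'   "tf", "report")`; default all.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("shapes", "stimgen", "train-nets",
                                    "behavior", "synth-eeg", "erp", "tf",
                                    "report")) {
  known <- c("shapes", "stimgen", "train-nets", "behavior", "synth-eeg",
             "erp", "tf", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  shapes <- enumerate_free_hexominoes()

  if ("shapes" %in% stages) {
    d <- file.path(out, "shapes")
    dir.create(d, showWarnings = FALSE)
    write_dictionary_json(shapes, file.path(d, "dictionary.json"))
    write_dictionary_sprites(shapes, file.path(d, "sprites.png"))
    write_manifest(d, "shapes", c("dictionary.json", "sprites.png"),
                   config, config$seed)
  }

  if ("stimgen" %in% stages) {
    d <- file.path(out, "stimuli")
    seed <- substream_seed(config$seed, "stimgen")
    split <- split_dictionary(shapes, 5L, seed)
    for (task in c("SD", "SR")) {
      trials <- generate_dataset(task, config$stimuli$n, shapes,
                                 split$train_ids, seed = substream_seed(seed, task),
                                 scale = config$stimuli$scale)
      sub <- trials[seq_len(min(config$stimuli$n_export_png, length(trials)))]
      attributes(sub) <- attributes(trials)
      write_stimulus_set(sub, file.path(d, task), prefix = tolower(task))
      full_manifest <- do.call(rbind, lapply(seq_along(trials), function(i) {
        tr <- trials[[i]]
        data.frame(trial = i, task = task, rho = tr$placement$rho,
                   theta = tr$placement$theta, axis = tr$placement$axis,
                   dx = tr$placement$dx, dy = tr$placement$dy,
                   item_a = tr$item_a, item_b = tr$item_b,
                   sd_label = tr$sd_label,
                   sr_label = ifelse(is.na(tr$sr_label), "", tr$sr_label))
      }))
      write.csv(full_manifest, file.path(d, sprintf("%s_trials.csv", tolower(task))),
                row.names = FALSE)
    }
    write_manifest(d, "stimgen", c("sd_trials.csv", "sr_trials.csv"),
                   config, seed)
  }

  if ("train-nets" %in% stages) {
    d <- file.path(out, "networks")
    dir.create(d, showWarnings = FALSE)
    seed <- substream_seed(config$seed, "train-nets")
    cfg <- network_config(learning_rate = config$networks$learning_rate,
                          epochs = config$networks$epochs_cnn)
    res <- run_dichotomy_experiment(
      n_reps = config$networks$n_reps, shapes = shapes, config = cfg,
      n_train = config$networks$n_train, n_val = config$networks$n_val,
      n_test = config$networks$n_test,
      epochs_by_arch = list(cnn = config$networks$epochs_cnn,
                            siamese = config$networks$epochs_siamese),
      seed = seed)
    write.csv(res, file.path(d, "results.csv"), row.names = FALSE)
    write.csv(summary(res), file.path(d, "summary.csv"), row.names = FALSE)
    write_manifest(d, "train-nets", c("results.csv", "summary.csv"),
                   config, seed)
  }

  if ("behavior" %in% stages) {
    d <- file.path(out, "behavior")
    dir.create(d, showWarnings = FALSE)
    seed <- substream_seed(config$seed, "behavior")
    log <- run_session(
      sim_observer(intensity_of(config$quest$rho_threshold, "rho")),
      sim_observer(intensity_of(config$quest$theta_threshold, "theta")),
      n_blocks = config$quest$n_blocks,
      trials_per_block = config$quest$trials_per_block, seed = seed)
    write.csv(as.data.frame(log), file.path(d, "session.csv"), row.names = FALSE)
    traces <- session_block_traces(log)
    write.csv(traces, file.path(d, "traces.csv"), row.names = FALSE)
    grDevices::png(file.path(d, "traces.png"), 900, 400)
    graphics::par(mfrow = c(1, 2))
    plot(traces$block, traces$rho, type = "b", xlab = "block",
         ylab = "rho (deg)", main = "SD staircase (rho)")
    plot(traces$block, traces$theta, type = "b", xlab = "block",
         ylab = "theta (deg)", main = "SR staircase (theta)")
    grDevices::dev.off()
    write_manifest(d, "behavior", c("session.csv", "traces.csv", "traces.png"),
                   config, seed)
  }

  mont <- eeg_montage()
  mont <- mont[mont$label %in% config$eeg$montage_labels, ]
  epochs_path <- file.path(out, "eeg", "epochs.bin")
  if ("synth-eeg" %in% stages) {
    d <- file.path(out, "eeg")
    dir.create(d, showWarnings = FALSE)
    seed <- substream_seed(config$seed, "synth-eeg")
    ep <- synthesize_epochs(config$eeg$n_subjects,
                            config$eeg$trials_per_condition,
                            effect_spec(), mont, sfreq = config$eeg$sfreq,
                            t_end = config$eeg$t_end, seed = seed)
    write_epochs(ep, epochs_path)
    write_manifest(d, "synth-eeg", "epochs.bin", config, seed)
  }

  if (any(c("erp", "tf") %in% stages)) {
    if (!file.exists(epochs_path))
      stop("missing upstream artifact: ", epochs_path,
           " (run the synth-eeg stage first)")
    ep <- read_epochs(epochs_path)
  }

  if ("erp" %in% stages) {
    d <- file.path(out, "erp")
    dir.create(d, showWarnings = FALSE)
    erps <- compute_erps(ep)
    mids <- intersect(midline_electrodes(), ep$ch_names)
    res <- erp_difference_test(erps, electrodes = mids, q = config$erp$q)
    write_erp_result(res, file.path(d, "erp_result.csv"))
    write.csv(erp_topography(erps), file.path(d, "topography.csv"),
              row.names = FALSE)
    grDevices::png(file.path(d, "erp_panels.png"), 1000, 700)
    graphics::par(mfrow = c(ceiling(length(mids) / 3), 3), mar = c(3, 3, 2, 1))
    for (i in seq_along(mids)) {
      plot(res$times, res$mean[i, ], type = "l", main = mids[i],
           xlab = "time (s)", ylab = "SD-SR (uV)")
      graphics::abline(h = 0, lty = 3)
      sig <- which(res$mask[i, ])
      if (length(sig)) graphics::points(res$times[sig], res$mean[i, sig],
                                        col = "red", pch = 16, cex = 0.4)
    }
    grDevices::dev.off()
    write_manifest(d, "erp", c("erp_result.csv", "topography.csv",
                               "erp_panels.png"), config,
                   substream_seed(config$seed, "synth-eeg"))
  }

  if ("tf" %in% stages) {
    d <- file.path(out, "tf")
    dir.create(d, showWarnings = FALSE)
    seed <- substream_seed(config$seed, "tf")
    spec <- wavelet_spec(n_freqs = config$tf$n_freqs,
                         f_range = c(config$tf$f_min, config$tf$f_max),
                         sfreq = ep$sfreq)
    maps <- condition_diff_maps(ep, spec, decim = config$tf$decim)
    res <- cluster_permutation_test(maps, cluster_config(
      t_threshold = config$tf$t_threshold,
      n_permutations = config$tf$n_permutations,
      alpha = config$tf$alpha, seed = seed))
    write_cluster_table(res, file.path(d, "cluster_table.csv"))
    es <- if (any(res$sig_mask))
      cluster_effect_size(maps, res$sig_mask)[c("t", "df", "p", "d")]
    else list(t = NA, df = NA, p = NA, d = NA)
    jsonlite::write_json(es, file.path(d, "effect_size.json"),
                         auto_unbox = TRUE, digits = NA)
    grDevices::png(file.path(d, "tf_panels.png"), 1000, 400)
    graphics::par(mfrow = c(1, 2))
    mean_map <- apply(maps, c(2, 3), mean)
    graphics::image(attr(maps, "times"), seq_along(spec$freqs), t(mean_map),
                    xlab = "time (s)", ylab = "freq index",
                    main = "mean SD-SR (dB)")
    graphics::abline(v = c(0, 0.35, 1.35), col = "white")
    graphics::image(attr(maps, "times"), seq_along(spec$freqs), t(res$t_map),
                    xlab = "time (s)", ylab = "freq index", main = "t map")
    if (any(res$sig_mask))
      graphics::contour(attr(maps, "times"), seq_along(spec$freqs),
                        t(res$sig_mask * 1), levels = 0.5, add = TRUE)
    grDevices::dev.off()
    write_manifest(d, "tf", c("cluster_table.csv", "effect_size.json",
                              "tf_panels.png"), config, seed)
  }

  if ("report" %in% stages) {
    d <- file.path(out, "report")
    dir.create(d, showWarnings = FALSE)
    lines <- c("# Pipeline report", "",
               sprintf("Seed: %d. Config hash: %s.", config$seed,
                       config_hash(config)), "")
    net_csv <- file.path(out, "networks", "summary.csv")
    if (file.exists(net_csv)) {
      s <- read.csv(net_csv)
      lines <- c(lines, "## Network generalization (test accuracy on held-out shapes)",
                 "", knit_table(s), "")
    }
    tr_csv <- file.path(out, "behavior", "traces.csv")
    if (file.exists(tr_csv))
      lines <- c(lines, "## Adaptive staircase",
                 "", "![traces](../behavior/traces.png)", "")
    if (file.exists(file.path(out, "erp", "erp_panels.png")))
      lines <- c(lines, "## ERP differences (midline electrodes)", "",
                 "![erp](../erp/erp_panels.png)", "")
    tf_json <- file.path(out, "tf", "effect_size.json")
    if (file.exists(tf_json)) {
      es <- jsonlite::fromJSON(tf_json)
      lines <- c(lines, "## Time-frequency cluster statistics", "",
                 "![tf](../tf/tf_panels.png)", "",
                 sprintf("Within-cluster effect: t(%s) = %s, p = %s, d = %s.",
                         es$df, format(es$t, digits = 4),
                         format(es$p, digits = 3), format(es$d, digits = 3)), "")
    }
    writeLines(lines, file.path(d, "report.md"))
    write_manifest(d, "report", "report.md", config, config$seed)
  }
  invisible(out)
}

## Minimal markdown table formatter for the report.
knit_table <- function(df) {
  fmt <- function(x) if (is.numeric(x)) formatC(x, digits = 3, format = "g") else as.character(x)
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    body)
}
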