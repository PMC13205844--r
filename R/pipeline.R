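#' @include synthetic-faces.R dataset.R net.R metrics.R equivalence.R
NULL

#' Pipeline configuration
#'
#' One flat configuration object for the end-to-end run; every default is
#' the study condition (98 subjects, 68/15/15 subject split, brightness
#' augmentation 0.7-1.3 doubling the training set, Adam 1e-4 / batch 16 /
#' 50 epochs with early stopping, 0.1 mm/px, 2 mm margin).
#'
#' @param n_subjects Cohort size.
#' @param master_seed Seed for cohort generation.
#' @param split_sizes Train/val/test subject counts.
#' @param split_seed Seed for the subject split.
#' @param augmentation An [augmentationConfig()].
#' @param train A [trainConfig()].
#' @param views Views to train (default both).
#' @param scale mm per pixel at original resolution.
#' @param thresholds CED threshold grid in mm.
#' @param margin_mm TOST equivalence margin.
#' @param alpha Significance level.
#' @param out_dir Output directory.
#' @return A list of class `"run_config"`.
#' @export
runConfig <- function(n_subjects = 98L, master_seed = 42L,
                      split_sizes = c(68L, 15L, 15L), split_seed = 42L,
                      augmentation = augmentationConfig(),
                      train = trainConfig(),
                      views = c("frontal", "profile"), scale = 0.1,
                      thresholds = c(2, 2.5, 3, 4), margin_mm = 2.0,
                      alpha = 0.05,
                      out_dir = tempfile("softmark_run_")) {
  structure(list(n_subjects = as.integer(n_subjects),
                 master_seed = as.integer(master_seed),
                 split_sizes = as.integer(split_sizes),
                 split_seed = as.integer(split_seed),
                 augmentation = augmentation, train = train, views = views,
                 scale = scale, thresholds = thresholds,
                 margin_mm = margin_mm, alpha = alpha, out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' simulate -> quality-control gate -> subject split (leakage-checked) ->
#' photometric augmentation of the training set -> preprocessing -> training
#' (per view) -> evaluation on the held-out test subjects -> equivalence
#' statistics. Every stage logs its input/output counts; all outputs,
#' the configuration, and the log are written under `cfg$out_dir`.
#'
#' @param cfg A [runConfig()].
#' @return Invisibly, a list with the split, trained nets, per-view
#'   evaluation (`errors`, `ced`, `equivalence`), and the log lines.
#' @export
runPipeline <- function(cfg = runConfig()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log <<- c(log, line)
    line
  }

  say("simulate: %d subjects -> %d images (seed %d)", cfg$n_subjects,
      2 * cfg$n_subjects, cfg$master_seed)
  cohort <- generateCohort(cfg$n_subjects, cfg$master_seed)

  qc <- qcGate(cohort)
  say("qc: %d of %d subjects pass quality control",
      length(unique(vapply(qc$images, subjectId, ""))), cfg$n_subjects)
  cohort <- qc$images

  ids <- unique(vapply(cohort, subjectId, ""))
  if (sum(cfg$split_sizes) != length(ids))
    stop(sprintf("stage split: sizes %s do not sum to %d subjects",
                 paste(cfg$split_sizes, collapse = "/"), length(ids)),
         call. = FALSE)
  split <- subjectSplit(ids, cfg$split_sizes, cfg$split_seed)
  leak <- assertNoLeakage(split, cohort)
  if (!leak$pass)
    stop(paste("stage split: leakage check failed:",
               paste(leak$problems, collapse = "; ")), call. = FALSE)
  say("split: %d/%d/%d subjects (train/val/test), leakage check passed",
      cfg$split_sizes[1], cfg$split_sizes[2], cfg$split_sizes[3])

  sets <- splitSets(split)
  results <- list()
  n_train_total <- 0L
  for (view in cfg$views) {
    tr_imgs <- .filter_images(cohort, sets$train, view)
    va_imgs <- .filter_images(cohort, sets$val, view)
    te_imgs <- .filter_images(cohort, sets$test, view)
    aug_cfg <- cfg$augmentation
    aug_cfg$seed <- .derive_seed(aug_cfg$seed, match(view, cfg$views), 3L)
    tr_aug <- augmentTrainingSet(tr_imgs, aug_cfg)
    n_train_total <- n_train_total + length(tr_aug)
    say("augment[%s]: %d original + %d augmented = %d training images",
        view, length(tr_imgs), length(tr_aug) - length(tr_imgs),
        length(tr_aug))
    tr_s <- lapply(tr_aug, resizeNormalize)
    va_s <- lapply(va_imgs, resizeNormalize)
    net <- buildModel(landmarkSchema(view), init_seed = cfg$train$data_seed)
    say("train[%s]: fitting %s parameters on %d samples", view,
        format(countParameters(net), big.mark = ","), length(tr_s))
    net <- trainModel(net, tr_s, va_s, cfg$train)
    say("train[%s]: %d epochs run, best validation epoch %d", view,
        nrow(net@history), net@trainConfig$best_epoch)

    preds <- lapply(te_imgs, function(im) predictLandmarks(net, im))
    ev <- perLandmarkErrors(te_imgs, preds, cfg$scale)
    ced <- cedCurve(ev$table$error_mm, cfg$thresholds)
    eq <- equivalenceReport(ev$table$error_mm, cfg$margin_mm, cfg$alpha)
    say("evaluate[%s]: %d test images, mean error %.3f mm, SR@2mm %.2f%%",
        view, length(te_imgs), ev$overall$mean_mm, 100 * ced$sr_clinical)

    utils::write.csv(ev$table,
                     file.path(cfg$out_dir, sprintf("errors_%s.csv", view)),
                     row.names = FALSE)
    utils::write.csv(ev$per_landmark,
                     file.path(cfg$out_dir,
                               sprintf("per_landmark_%s.csv", view)),
                     row.names = FALSE)
    utils::write.csv(net@history,
                     file.path(cfg$out_dir, sprintf("history_%s.csv", view)),
                     row.names = FALSE)
    results[[view]] <- list(net = net, errors = ev, ced = ced,
                            equivalence = eq, n_test = length(te_imgs))
  }
  say("training total across views: %d images; cohort total %d images",
      n_train_total,
      n_train_total + 2L * (cfg$split_sizes[2] + cfg$split_sizes[3]))

  metrics <- lapply(results, function(r) {
    list(mean_error_mm = r$errors$overall$mean_mm,
         sd_error_mm = r$errors$overall$sd_mm,
         sr = as.list(setNames(r$ced$success_rates,
                               paste0("sr_", r$ced$thresholds, "mm"))),
         auc_ced = r$ced$auc_ced,
         tost_p = r$equivalence$tost$p_tost,
         equivalent = r$equivalence$tost$equivalent,
         ba_bias_mm = r$equivalence$bland_altman$bias_mm,
         ba_loa = c(r$equivalence$bland_altman$loa_lower,
                    r$equivalence$bland_altman$loa_upper))
  })
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg_out <- cfg
  cfg_out$augmentation <- unclass(cfg_out$augmentation)
  cfg_out$train <- unclass(cfg_out$train)
  jsonlite::write_json(unclass(cfg_out),
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log, file.path(cfg$out_dir, "log.txt"))
  invisible(list(split = split, results = results, metrics = metrics,
                 log = log, out_dir = cfg$out_dir))
}

.md_table <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) formatC(v, digits = digits,
                                                 format = "g"))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "),
                                         "|"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Render a human-readable report for a completed run
#'
#' Produces markdown tables mirroring the standard reporting layout:
#' per-landmark mean errors with p-values for each view, success rates and
#' AUC-CED, and the TOST / Bland-Altman equivalence summary; written to
#' `report.md` in the run directory.
#'
#' @param out_dir Directory produced by [runPipeline()].
#' @return Invisibly, the report text.
#' @export
renderReport <- function(out_dir) {
  mpath <- file.path(out_dir, "metrics.json")
  .stop_if(!file.exists(mpath), "no metrics.json: incomplete run")
  metrics <- jsonlite::fromJSON(mpath, simplifyVector = TRUE)
  parts <- c("# Landmark detection evaluation report", "")
  for (view in names(metrics)) {
    per_path <- file.path(out_dir, sprintf("per_landmark_%s.csv", view))
    .stop_if(!file.exists(per_path),
             sprintf("missing per-landmark table for %s", view))
    per <- utils::read.csv(per_path)
    parts <- c(parts, sprintf("## Per-landmark errors (%s view)", view), "",
               .md_table(per), "")
  }
  sr_rows <- do.call(rbind, lapply(names(metrics), function(view) {
    m <- metrics[[view]]
    data.frame(view = view, mean_error_mm = m$mean_error_mm,
               as.list(unlist(m$sr)), auc_ced = m$auc_ced)
  }))
  parts <- c(parts, "## Success rates and AUC-CED", "", .md_table(sr_rows),
             "")
  eq_rows <- do.call(rbind, lapply(names(metrics), function(view) {
    m <- metrics[[view]]
    data.frame(view = view, mean_error_mm = m$mean_error_mm,
               sd_mm = m$sd_error_mm, tost_p = m$tost_p,
               ba_bias_mm = m$ba_bias_mm, loa_lower = m$ba_loa[1],
               loa_upper = m$ba_loa[2])
  }))
  parts <- c(parts, "## Equivalence statistics", "", .md_table(eq_rows), "")
  text <- paste(parts, collapse = "\n")
  writeLines(text, file.path(out_dir, "report.md"))
  invisible(text)
}
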