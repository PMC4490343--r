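#' Read a multi-page grayscale TIFF as a frame stack
#'
#' Pages are read as float intensities in \[0, 1\]; colour pages are converted
#' to luminance (0.2126 R + 0.7152 G + 0.0722 B).
#'
#' @param path TIFF file path.
#' @param fps frame rate in frames per second (TIFF carries no timing).
#' @param metadata named list of labels attached to the stack.
#' @return a [frame_stack()].
#' @export
load_stack <- function(path, fps, metadata = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) stop("need >= 2 frames, got ", length(pages))
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3)
      0.2126 * p[, , 1] + 0.7152 * p[, , 2] + 0.0722 * p[, , 3]
    else p
  })
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1) stop("mixed page shapes in ", path)
  frame_stack(pages, fps = fps, metadata = metadata)
}

#' Write a frame stack as a multi-page grayscale TIFF
#'
#' Intensities are clipped to \[0, 1\] and stored at 16 bits per sample so a
#' write/read round trip preserves frames to better than 1/65535.
#'
#' @param stack a [frame_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[3]), function(k)
    pmin(pmax(stack$frames[, , k], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write a cohort to disk
#'
#' Videos become multi-page TIFFs, profiles and traces become two-column CSV
#' files, each acquisition gets a JSON ground-truth sidecar, and a manifest
#' CSV (well_id, condition, acquisition_index, path, fps) indexes everything.
#'
#' @param cohort a cohort from [make_cohort()] or [make_trace_cohort()].
#' @param dir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$path <- NA_character_
  man$fps <- NA_real_
  for (i in seq_along(cohort$acquisitions)) {
    a <- cohort$acquisitions[[i]]
    stem <- sprintf("%s_%s_%02d", a$well_id, a$condition, a$acquisition_index)
    d <- a$data
    if (inherits(d, "frame_stack")) {
      p <- file.path(dir, paste0(stem, ".tif"))
      write_stack(d, p)
      man$fps[i] <- d$fps
    } else if (inherits(d, "contractile_profile")) {
      p <- file.path(dir, paste0(stem, "_profile.csv"))
      utils::write.csv(data.frame(time = d$times, score = d$score), p,
                       row.names = FALSE)
      man$fps[i] <- 1 / stats::median(diff(d$times))
    } else {
      p <- file.path(dir, paste0(stem, "_trace.csv"))
      utils::write.csv(data.frame(time = d$times, intensity = d$raw), p,
                       row.names = FALSE)
      man$fps[i] <- 1 / stats::median(diff(d$times))
    }
    man$path[i] <- p
    truth <- a$truth
    truth$fn <- NULL  # closures do not serialise
    jsonlite::write_json(truth, file.path(dir, paste0(stem, "_truth.json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read a cohort manifest
#'
#' @param path manifest CSV with columns well_id, condition,
#'   acquisition_index, path, fps.
#' @return the manifest data.frame, with paths resolved relative to the
#'   manifest's directory and checked for uniqueness.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "condition", "acquisition_index", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  key <- paste(man$well_id, man$condition, man$acquisition_index)
  if (anyDuplicated(key))
    stop("duplicate (well_id, condition, acquisition_index) in manifest")
  rel <- !file.exists(man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  man
}

#' Pipeline run configuration
#'
#' @param block_size flow-averaging block edge, pixels.
#' @param prominence beat-peak prominence fraction.
#' @param repeats SVM split repeats.
#' @param seed master seed.
#' @param grid SVM hyperparameter grid.
#' @param strict_split well-level disjoint splitting flag.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(block_size = 20L, prominence = 0.1, repeats = 50L,
                       seed = 1L, grid = default_svm_grid(),
                       strict_split = FALSE) {
  structure(list(block_size = as.integer(block_size), prominence = prominence,
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 grid = grid, strict_split = strict_split),
            class = "run_config")
}

# order-independent config/seed fingerprint carried in output headers
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(unclass(config)))]), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

write_csv_stamped <- function(df, path, config, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cardioflow seed=%d config=%s%s", config$seed,
                     config_hash(config),
                     if (is.null(extra)) "" else paste0(" ", extra)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the brightfield screening pipeline over a cohort
#'
#' For every non-baseline condition: compute contractile profiles (via
#' optical flow for video acquisitions), segment beats, extract features,
#' and run the repeated-split SVM protocol against the pooled baseline
#' acquisitions. Conditions with fewer than 3 wells of usable features are
#' skipped with a report entry rather than aborting the run.
#'
#' @param cohort a cohort from [make_cohort()], or a manifest data.frame from
#'   [read_manifest()] pointing at stacks/profiles on disk.
#' @param config a [run_config()].
#' @param out_dir optional directory for profile/feature/summary artifacts.
#' @return list with `summary` (data.frame: condition, mean_accuracy,
#'   sem_accuracy, n_train range, status), `results` (per-condition
#'   [svm_accuracy()] objects), and `features` (the pooled feature table).
#' @export
run_screen <- function(cohort, config = run_config(), out_dir = NULL) {
  features <- if (inherits(cohort, "cohort")) {
    cohort_features(cohort, block = config$block_size)
  } else {
    manifest_features(cohort, config)
  }
  conds <- setdiff(unique(features$condition), "baseline")
  if (length(conds) == 0) stop("cohort has no non-baseline conditions")
  results <- list()
  rows <- NULL
  for (cn in conds) {
    sub <- features[features$condition %in% c("baseline", cn), , drop = FALSE]
    n_wells_cond <- length(unique(sub$well_id[sub$condition == cn]))
    if (n_wells_cond < 3) {
      rows <- rbind(rows, data.frame(condition = cn, mean_accuracy = NA,
                                     sem_accuracy = NA, status = "skipped: <3 wells"))
      next
    }
    res <- svm_accuracy(sub, repeats = config$repeats, seed = config$seed,
                        grid = config$grid, strict = config$strict_split)
    results[[cn]] <- res
    rows <- rbind(rows, data.frame(condition = cn,
                                   mean_accuracy = res$mean_accuracy,
                                   sem_accuracy = res$sem_accuracy,
                                   status = "ok"))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_csv_stamped(features, file.path(out_dir, "features.csv"), config)
    write_csv_stamped(rows, file.path(out_dir, "screen_summary.csv"), config)
  }
  list(summary = rows, results = results, features = features)
}

# feature table from an on-disk manifest (TIFF stacks or profile CSVs)
manifest_features <- function(manifest, config) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    f <- tryCatch({
      pr <- if (grepl("\\.tiff?$", m$path, ignore.case = TRUE)) {
        st <- load_stack(m$path, fps = m$fps)
        fl <- compute_flow(st)
        profile_from_flow(block_average(fl, min(config$block_size,
                                                dim(fl$u)[1], dim(fl$u)[2])))
      } else {
        d <- utils::read.csv(m$path, comment.char = "#")
        contractile_profile(d$score, d$time)
      }
      ft <- beat_features(pr, segment_beats(pr, prominence = config$prominence))
      ft$well_id <- m$well_id
      ft$condition <- m$condition
      ft$acquisition_index <- m$acquisition_index
      ft
    }, error = function(e) {
      warning("acquisition ", m$path, " failed: ", conditionMessage(e))
      NULL
    })
    f
  })
  ml_table(do.call(rbind, rows))
}

#' Run the calcium pipeline and repeated-measures statistics over a cohort
#'
#' Computes per-acquisition transient metrics, builds wells-by-conditions
#' matrices of beating rate and SR90 (baseline = mean over the baseline
#' acquisitions per well), and applies the repeated-measures ANOVA with
#' conditional Greenhouse-Geisser correction plus Dunnett comparisons to
#' each metric. Statistics are skipped with a message when the
#' wells-by-conditions matrix is incomplete.
#'
#' @param cohort a trace cohort from [make_trace_cohort()], or a manifest
#'   data.frame whose paths are trace CSVs (time, intensity).
#' @param config a [run_config()].
#' @return list with `metrics` (per-acquisition data.frame), `matrices`
#'   (wells x conditions, one per metric) and `stats` (per metric:
#'   rm_anova + dunnett, or NULL if skipped).
#' @export
run_calcium <- function(cohort, config = run_config()) {
  if (inherits(cohort, "cohort")) {
    man <- cohort$manifest
    traces <- lapply(cohort$acquisitions, `[[`, "data")
  } else {
    man <- cohort
    if (nrow(man) == 0) stop("empty manifest")
    traces <- lapply(man$path, function(p) {
      d <- utils::read.csv(p, comment.char = "#")
      calcium_trace(d$intensity, d$time)
    })
  }
  if (length(traces) == 0) stop("empty manifest")
  rows <- NULL
  for (i in seq_along(traces)) {
    m <- tryCatch(transient_metrics(detrend_bleach(detect_transients(traces[[i]]))),
                  error = function(e) NULL)
    rows <- rbind(rows, data.frame(
      well_id = man$well_id[i], condition = man$condition[i],
      acquisition_index = man$acquisition_index[i],
      beating_rate = if (is.null(m)) NA_real_ else m$beating_rate,
      amplitude = if (is.null(m)) NA_real_ else m$amplitude,
      ctd90 = if (is.null(m)) NA_real_ else m$ctd90,
      sr90 = if (is.null(m)) NA_real_ else m$sr90))
  }
  build_matrix <- function(metric) {
    agg <- stats::aggregate(rows[[metric]],
                            by = list(well = rows$well_id,
                                      condition = rows$condition),
                            FUN = mean)
    conds <- c("baseline", setdiff(unique(rows$condition), "baseline"))
    wells <- sort(unique(rows$well_id))
    M <- matrix(NA_real_, length(wells), length(conds),
                dimnames = list(wells, conds))
    for (r in seq_len(nrow(agg)))
      M[agg$well[r], agg$condition[r]] <- agg$x[r]
    M
  }
  out_stats <- list()
  matrices <- list()
  for (metric in c("beating_rate", "sr90")) {
    M <- build_matrix(metric)
    matrices[[metric]] <- M
    if (any(!is.finite(M))) {
      message("incomplete wells x conditions matrix for ", metric,
              ": statistics skipped")
      out_stats[[metric]] <- NULL
      next
    }
    d <- rm_dataset(M, baseline = "baseline")
    out_stats[[metric]] <- list(anova = rm_anova(d), dunnett = dunnett_test(d))
  }
  list(metrics = rows, matrices = matrices, stats = out_stats)
}
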