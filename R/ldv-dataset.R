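#' An experimental run
#'
#' One experimental unit: a 1-s unstimulated trace paired with a 1-s
#' stimulated trace, the LDV backscatter diagnostic channel, and the animal
#' metadata. Recordings alternate unstimulated and stimulated sections; each
#' run pairs one of each.
#'
#' @param run_id unique run identifier.
#' @param unstim,stim [ldv_trace()] objects, 1 s each (stim may be `NULL` for
#'   `stimulus_kind = "none"`).
#' @param stimulus_kind one of `"upchirp"`, `"downchirp"`, `"force_step"`,
#'   `"none"`.
#' @param backscatter numeric diagnostic series (arbitrary units), or `NULL`.
#' @param metadata named list; recognised fields: `animal_id`, `sex`,
#'   `genotype`, `zt`, `stage`, `compound`.
#' @param flagged logical; `TRUE` when segmentation could not supply a full
#'   pre-stimulus second.
#' @param flag_reason character reason when flagged.
#' @return An `ldv_run` object.
#' @export
ldv_run <- function(run_id, unstim, stim = NULL,
                    stimulus_kind = c("upchirp", "downchirp", "force_step", "none"),
                    backscatter = NULL, metadata = list(),
                    flagged = FALSE, flag_reason = NA_character_) {
  stimulus_kind <- match.arg(stimulus_kind)
  if (!is.null(unstim)) stopifnot(inherits(unstim, "ldv_trace"))
  if (!is.null(stim)) stopifnot(inherits(stim, "ldv_trace"))
  if (stimulus_kind != "none" && is.null(stim) && !flagged) {
    stop("run ", run_id, ": stimulus_kind '", stimulus_kind,
         "' requires a stimulated trace")
  }
  structure(list(run_id = as.character(run_id), unstim = unstim, stim = stim,
                 stimulus_kind = stimulus_kind, backscatter = backscatter,
                 metadata = metadata, flagged = flagged,
                 flag_reason = flag_reason),
            class = "ldv_run")
}

#' @export
print.ldv_run <- function(x, ...) {
  cat(sprintf("<ldv_run> %s [%s]%s\n", x$run_id, x$stimulus_kind,
              if (isTRUE(x$flagged)) paste0(" FLAGGED: ", x$flag_reason) else ""))
  invisible(x)
}

#' Segment a continuous recording into runs
#'
#' The experimental structure interleaves unstimulated and stimulated 1-s
#' sections. Each stimulus epoch (from the marker table) is paired with the
#' immediately preceding second of unstimulated recording; mirrored up/down
#' chirp pairs keep their temporal order.
#'
#' @param recording list with elements `fs` (Hz), `displacement` (nm),
#'   `backscatter` (same length, may be `NULL`) and `markers`, a data frame
#'   with columns `onset_s` and `kind` (one of `"upchirp"`, `"downchirp"`,
#'   `"force_step"`), one row per 1-s stimulus epoch.
#' @param section_s section duration, s (default 1).
#' @param metadata named list copied onto every run.
#' @param id_prefix prefix for generated run ids.
#' @return List of [ldv_run()] in marker order. Runs without a full
#'   pre-stimulus second are flagged, never dropped.
#' @export
segment_runs <- function(recording, section_s = 1, metadata = list(),
                         id_prefix = "run") {
  stopifnot(is.list(recording), !is.null(recording$fs),
            !is.null(recording$displacement), !is.null(recording$markers))
  mk <- recording$markers
  if (nrow(mk) == 0) return(list())
  mk <- mk[order(mk$onset_s), , drop = FALSE]
  fs <- recording$fs
  n_total <- length(recording$displacement)
  if (any(diff(mk$onset_s) < section_s - 1e-9)) {
    stop("overlapping stimulus epochs in marker table")
  }
  nsec <- round(fs * section_s)
  runs <- vector("list", nrow(mk))
  for (i in seq_len(nrow(mk))) {
    on_i <- round(mk$onset_s[i] * fs) + 1L
    stim_idx <- on_i:(on_i + nsec - 1L)
    if (max(stim_idx) > n_total) stop("stimulus epoch ", i, " runs past the recording")
    stim <- ldv_trace(recording$displacement[stim_idx], fs, t0 = mk$onset_s[i])
    flagged <- FALSE
    reason <- NA_character_
    unstim <- NULL
    pre_start <- on_i - nsec
    prev_end <- if (i > 1) round(mk$onset_s[i - 1] * fs) + nsec else 0L
    if (pre_start < 1L || pre_start <= prev_end) {
      flagged <- TRUE
      reason <- "missing pre-stimulus second"
    } else {
      unstim <- ldv_trace(recording$displacement[pre_start:(on_i - 1L)], fs,
                          t0 = mk$onset_s[i] - section_s)
    }
    bsc <- if (!is.null(recording$backscatter)) recording$backscatter[stim_idx] else NULL
    runs[[i]] <- ldv_run(sprintf("%s%03d", id_prefix, i), unstim, stim,
                         stimulus_kind = as.character(mk$kind[i]),
                         backscatter = bsc, metadata = metadata,
                         flagged = flagged, flag_reason = reason)
  }
  runs
}

#' Curate runs by the LDV backscatter diagnostic
#'
#' A run passes when the laser stayed on the flagellum throughout: the
#' fraction of backscatter samples below `backscatter_threshold` must not
#' exceed `floor_fraction`. Runs without a diagnostic channel fail with reason
#' `"no diagnostic"`. Every exclusion is reported; traces are never mutated.
#'
#' @param runs list of [ldv_run()].
#' @param backscatter_threshold backscatter level below which a sample counts
#'   as laser dropout; default 20% of the maximum observed across all runs.
#' @param floor_fraction maximum tolerated fraction of dropout samples
#'   (default 0.05).
#' @return List with `kept` (runs passing curation) and `report`, a data frame
#'   (run_id, passed, reason, backscatter_floor_fraction).
#' @export
curate_runs <- function(runs, backscatter_threshold = NULL,
                        floor_fraction = 0.05) {
  if (is.null(backscatter_threshold)) {
    mx <- suppressWarnings(max(unlist(lapply(runs, function(r) r$backscatter)),
                               na.rm = TRUE))
    backscatter_threshold <- if (is.finite(mx)) 0.2 * mx else 0
  }
  rows <- lapply(runs, function(r) {
    if (is.null(r$backscatter)) {
      data.frame(run_id = r$run_id, passed = FALSE, reason = "no diagnostic",
                 backscatter_floor_fraction = NA_real_)
    } else {
      frac <- mean(r$backscatter < backscatter_threshold)
      ok <- frac <= floor_fraction
      data.frame(run_id = r$run_id, passed = ok,
                 reason = if (ok) "" else "laser dropout",
                 backscatter_floor_fraction = frac)
    }
  })
  report <- do.call(rbind, rows)
  list(kept = runs[report$passed], report = report)
}

manifest_cols <- c("run_id", "animal_id", "sex", "genotype", "zt", "stage",
                   "compound", "stimulus_kind", "path")

#' Write a run collection to disk
#'
#' Writes one TSV per run (columns `time_s`, `unstim_nm`, `stim_nm`,
#' `backscatter`; absent channels written as NA) plus a manifest TSV listing
#' run id, metadata and file path. The round trip through [read_dataset()]
#' preserves samples to stored precision and metadata exactly.
#'
#' @param runs list of [ldv_run()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(runs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(runs, function(r) r$run_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate run_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- lapply(runs, function(r) {
    path <- paste0(r$run_id, ".tsv")
    n <- max(length(r$unstim$samples), length(r$stim$samples),
             length(r$backscatter))
    pad <- function(v) c(v, rep(NA_real_, n - length(v)))
    fs <- if (!is.null(r$unstim)) r$unstim$fs else r$stim$fs
    df <- data.frame(time_s = (seq_len(n) - 1L) / fs,
                     unstim_nm = pad(if (is.null(r$unstim)) numeric(0) else r$unstim$samples),
                     stim_nm = pad(if (is.null(r$stim)) numeric(0) else r$stim$samples),
                     backscatter = pad(if (is.null(r$backscatter)) numeric(0) else r$backscatter))
    utils::write.table(df, file.path(dir, path), sep = "\t", row.names = FALSE,
                       quote = FALSE)
    md <- r$metadata
    gv <- function(f) if (is.null(md[[f]])) NA_character_ else as.character(md[[f]])
    data.frame(run_id = r$run_id, animal_id = gv("animal_id"), sex = gv("sex"),
               genotype = gv("genotype"), zt = gv("zt"), stage = gv("stage"),
               compound = gv("compound"), stimulus_kind = r$stimulus_kind,
               path = path, fs = fs)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Read a run collection from a manifest
#'
#' @param manifest_path path to a manifest TSV written by [write_dataset()].
#' @return List of [ldv_run()].
#' @export
read_dataset <- function(manifest_path) {
  manifest <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                                colClasses = "character")
  if (nrow(manifest) == 0) return(list())
  if (anyDuplicated(manifest$run_id)) {
    stop("duplicate run_id in manifest: ",
         paste(unique(manifest$run_id[duplicated(manifest$run_id)]), collapse = ", "))
  }
  dir <- dirname(manifest_path)
  missing <- manifest$path[!file.exists(file.path(dir, manifest$path))]
  if (length(missing)) {
    stop("manifest references missing files: ", paste(missing, collapse = ", "))
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    df <- utils::read.table(file.path(dir, row$path), sep = "\t", header = TRUE)
    fs <- as.numeric(row$fs)
    getcol <- function(col) {
      v <- df[[col]]
      v <- v[!is.na(v)]
      if (length(v) == 0) NULL else v
    }
    un <- getcol("unstim_nm")
    st <- getcol("stim_nm")
    ldv_run(row$run_id,
            unstim = if (is.null(un)) NULL else ldv_trace(un, fs),
            stim = if (is.null(st)) NULL else ldv_trace(st, fs),
            stimulus_kind = row$stimulus_kind,
            backscatter = getcol("backscatter"),
            metadata = list(animal_id = row$animal_id, sex = row$sex,
                            genotype = row$genotype, zt = row$zt,
                            stage = row$stage, compound = row$compound))
  })
}
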