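#' @importFrom utils read.csv write.csv modifyList
NULL

#' Write a synthetic cohort to the pipeline's input formats
#'
#' Emits the trace CSV (pixel coordinates), the metadata JSON and the
#' ground-truth table consumed / checked by [run_pipeline()]. Coordinates
#' are converted to pixels with the given image scale, and the scale
#' reference object (a 10 mm plastic tube) is recorded in the metadata so
#' the pipeline must recover the scale itself.
#'
#' @param cohort a `ring_cohort` from [generate_cohort()].
#' @param dir output directory, created if missing.
#' @param mm_per_px image scale used to rasterize coordinates
#'   (default 0.02 mm/px).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, mm_per_px = 0.02) {
  stopifnot(inherits(cohort, "ring_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  meta_specs <- list()
  for (rec in cohort$specimens) {
    states_closed <- list()
    for (st in names(rec$states)) {
      g <- rec$states[[st]]
      states_closed[[st]] <- g$truth$closed
      for (border in c("inner", "outer")) {
        pts <- g[[border]]$points / mm_per_px
        rows[[length(rows) + 1L]] <- data.frame(
          specimen_id = rec$specimen_id, time_state = st, border = border,
          point_index = seq_len(nrow(pts)),
          x_px = pts[, 1L], y_px = pts[, 2L], stringsAsFactors = FALSE)
      }
    }
    meta_specs[[length(meta_specs) + 1L]] <- list(
      specimen_id = rec$specimen_id, patient_id = rec$patient_id,
      layer = rec$layer, protocol = rec$protocol,
      thickness_readings_mm = round(rec$thickness_readings, 4),
      a_pct = rec$a_pct, residual_media_fraction = rec$f,
      seed = rec$spec$seed, closed = states_closed)
  }
  traces <- do.call(rbind, rows)
  paths <- c(traces = file.path(dir, "traces.csv"),
             metadata = file.path(dir, "metadata.json"),
             truth = file.path(dir, "truth_table.csv"))
  write.csv(traces, paths[["traces"]], row.names = FALSE)
  meta <- list(
    scale = list(measured_px = 10 / mm_per_px, known_mm = 10,
                 description = "plastic tube of known 10 mm diameter"),
    specimens = meta_specs)
  jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE,
                       digits = NA, na = "null")
  write.csv(cohort$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}

#' Read a trace CSV
#'
#' @param path CSV with columns `specimen_id`, `time_state`, `border`,
#'   `point_index`, `x_px`, `y_px`.
#' @return data.frame of traces.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  tr <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("specimen_id", "time_state", "border", "point_index",
                "x_px", "y_px")
  missing <- setdiff(required, names(tr))
  if (length(missing) > 0L) {
    stop(path, ": missing columns ", paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(tr$x_px) | !is.finite(tr$y_px))
  if (length(bad) > 0L) {
    stop(path, ": malformed coordinate at line ", bad[1L] + 1L)
  }
  tr
}

#' Read a cohort metadata JSON
#'
#' @param path metadata file written by [write_cohort()] (or hand-authored
#'   in the same schema).
#' @return list with `scale` and `specimens`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(meta$scale) || is.null(meta$specimens)) {
    stop(path, ": metadata must contain `scale` and `specimens`")
  }
  meta
}

#' Validate pipeline input files
#'
#' Schema- and sanity-checks trace and metadata files without stopping on
#' the first problem; every issue becomes a row of the report.
#'
#' @param traces_path path to the trace CSV.
#' @param metadata_path path to the metadata JSON.
#' @return object of class `validation_report`: data.frame `problems`
#'   (file, specimen_id, issue) and data.frame `counts` (specimens per
#'   layer / protocol / state).
#' @export
validate_inputs <- function(traces_path, metadata_path) {
  problems <- list()
  note <- function(file, id, issue) {
    problems[[length(problems) + 1L]] <<- data.frame(
      file = file, specimen_id = id, issue = issue, stringsAsFactors = FALSE)
  }
  tr <- tryCatch(read_traces(traces_path), error = function(e) {
    note(traces_path, NA_character_, conditionMessage(e)); NULL
  })
  meta <- tryCatch(read_metadata(metadata_path), error = function(e) {
    note(metadata_path, NA_character_, conditionMessage(e)); NULL
  })
  counts <- data.frame()
  if (!is.null(meta)) {
    sc <- meta$scale
    if (is.null(sc$measured_px) || is.null(sc$known_mm) ||
        sc$measured_px <= 0 || sc$known_mm <= 0) {
      note(metadata_path, NA_character_, "invalid scale reference")
    }
    tab <- list()
    for (sp in meta$specimens) {
      id <- sp$specimen_id %||% NA_character_
      if (!isTRUE(sp$layer %in% c("I", "MI", "A"))) {
        note(metadata_path, id, paste0("unknown layer code: ", sp$layer))
      }
      if (!isTRUE(sp$protocol %in% c(1, 2))) {
        note(metadata_path, id, paste0("unknown protocol: ", sp$protocol))
      }
      for (st in names(sp$closed)) {
        if (!st %in% names(.state_times)) {
          note(metadata_path, id, paste0("unknown time state: ", st))
        }
        tab[[length(tab) + 1L]] <- data.frame(
          layer = sp$layer, protocol = sp$protocol, time_state = st,
          stringsAsFactors = FALSE)
      }
    }
    if (length(tab) > 0L) {
      counts <- as.data.frame(table(do.call(rbind, tab)),
                              stringsAsFactors = FALSE)
      counts <- counts[counts$Freq > 0L, , drop = FALSE]
    }
  }
  if (!is.null(tr)) {
    key <- interaction(tr$specimen_id, tr$time_state, tr$border, drop = TRUE)
    npts <- table(key)
    small <- names(npts)[npts < 4L]
    for (s in small) note(traces_path, s, "too few points (< 4)")
    if (!all(tr$border %in% c("inner", "outer"))) {
      note(traces_path, NA_character_, "border must be 'inner' or 'outer'")
    }
    if (!is.null(meta)) {
      ids_meta <- vapply(meta$specimens, function(s) s$specimen_id, "")
      orphans <- setdiff(unique(tr$specimen_id), ids_meta)
      for (o in orphans) note(traces_path, o, "specimen missing from metadata")
    }
  }
  structure(list(
    problems = if (length(problems) > 0L) do.call(rbind, problems)
               else data.frame(file = character(), specimen_id = character(),
                               issue = character()),
    counts = counts), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  np <- nrow(x$problems)
  cat("<validation_report>", np, "problem(s)\n")
  if (np > 0L) print(x$problems)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
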