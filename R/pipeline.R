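#' Pipeline run configuration
#'
#' @param traces path to the trace CSV.
#' @param metadata path to the metadata JSON.
#' @param out_dir optional output directory; when given, result tables, the
#'   JSON stats bundle and the log are written there.
#' @param degree,smoothing spline settings; the smoothing default (0.03 mm
#'   RMS) matches the expected manual-tracing noise (~0.02 mm per
#'   coordinate).
#' @param n_resample equidistant resampling points (default 40).
#' @param alpha significance level for every gate and test (default 0.05).
#' @param merge_protocols `"auto"` applies the merge decision (merge unless
#'   some parameter differs significantly between protocols); `TRUE`/`FALSE`
#'   force the outcome.
#' @param one_per_patient keep only the first specimen per patient x layer,
#'   avoiding repeated-specimen bias.
#' @param holm apply Holm correction across the protocol comparisons.
#' @param digits decimal places in formatted summaries (default 3, the
#'   published table's precision for curvatures).
#' @return object of class `run_config`.
#' @export
run_config <- function(traces, metadata, out_dir = NULL, degree = 3L,
                       smoothing = 0.03, n_resample = 40L, alpha = 0.05,
                       merge_protocols = "auto", one_per_patient = FALSE,
                       holm = FALSE, digits = 3L) {
  if (n_resample < 5L) stop("`n_resample` must be at least 5")
  structure(list(traces = traces, metadata = metadata, out_dir = out_dir,
                 degree = as.integer(degree), smoothing = smoothing,
                 n_resample = as.integer(n_resample), alpha = alpha,
                 merge_protocols = merge_protocols,
                 one_per_patient = one_per_patient, holm = holm,
                 digits = as.integer(digits)),
            class = "run_config")
}

.final_state <- function(protocol, layer) {
  if (protocol == 1L) {
    if (layer == "I") "cut_16h" else "separate_6h"
  } else "cut_22h"
}

# measure all specimens: one row per specimen x state
.measure_all <- function(tr, meta, config, logf) {
  scale <- scale_from_reference(meta$scale$measured_px, meta$scale$known_mm)
  rows <- list()
  for (sp in meta$specimens) {
    id <- sp$specimen_id
    thick <- tryCatch(mean_thickness(unlist(sp$thickness_readings_mm)),
                      error = function(e) NA_real_)
    for (st in names(sp$closed)) {
      closed <- isTRUE(sp$closed[[st]])
      sub <- tr[tr$specimen_id == id & tr$time_state == st, , drop = FALSE]
      geom <- tryCatch({
        mk <- function(border) {
          b <- sub[sub$border == border, , drop = FALSE]
          b <- b[order(b$point_index), , drop = FALSE]
          apply_scale(boundary_trace(cbind(b$x_px, b$y_px), border,
                                     closed = closed, units = "px"), scale)
        }
        suppressWarnings(segment_geometry(
          mk("inner"), mk("outer"), degree = config$degree,
          smoothing = config$smoothing, n = config$n_resample,
          time_state = st))
      }, error = function(e) {
        logf("specimen %s state %s discarded: %s", id, st,
             conditionMessage(e))
        NULL
      })
      if (is.null(geom)) next
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = id, patient_id = sp$patient_id, layer = sp$layer,
        protocol = as.integer(sp$protocol), time_state = st,
        closed = closed,
        kappa_in = geom$inner$curvature$mean_kappa,
        kappa_out = geom$outer$curvature$mean_kappa,
        radius_in = geom$inner$curvature$mean_radius,
        radius_out = geom$outer$curvature$mean_radius,
        length_in = geom$inner$length_mm,
        length_out = geom$outer$length_mm,
        phi_deg = geom$opening_angle_deg,
        thickness_mean = thick,
        a_pct = as.numeric(sp$a_pct %||% NA_real_),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# fill A% from matched A/MI thickness means where metadata did not carry it
.fill_a_pct <- function(ps) {
  need <- ps$layer %in% c("A", "MI") & is.na(ps$a_pct)
  if (!any(need)) return(ps)
  key <- paste(ps$patient_id, ps$protocol)
  for (i in which(need)) {
    other <- if (ps$layer[i] == "A") "MI" else "A"
    j <- which(key == key[i] & ps$layer == other)
    if (length(j) == 0L) next
    t_a <- if (ps$layer[i] == "A") ps$thickness_mean[i]
           else ps$thickness_mean[j[1L]]
    t_mi <- if (ps$layer[i] == "A") ps$thickness_mean[j[1L]]
            else ps$thickness_mean[i]
    if (is.finite(t_a) && is.finite(t_mi) && t_a > 0 && t_mi > 0) {
      ps$a_pct[i] <- adventitia_percentage(t_a, t_mi)
    }
  }
  ps
}

.strain_table <- function(ps, logf) {
  rows <- list()
  for (id in unique(ps$specimen_id)) {
    s <- ps[ps$specimen_id == id, , drop = FALSE]
    fin_state <- .final_state(s$protocol[1L], s$layer[1L])
    ring <- s[s$time_state == "ring", , drop = FALSE]
    fin <- s[s$time_state == fin_state, , drop = FALSE]
    if (nrow(ring) != 1L || nrow(fin) != 1L) {
      logf("specimen %s excluded from strain analysis: missing %s state",
           id, if (nrow(ring) != 1L) "ring" else fin_state)
      next
    }
    e_in <- boundary_strain(ring$length_in, fin$length_in, "inner",
                            specimen_id = id, final_state = fin_state)
    e_out <- boundary_strain(ring$length_out, fin$length_out, "outer",
                             specimen_id = id, final_state = fin_state)
    dec <- strain_decomposition(e_in, e_out)
    rows[[length(rows) + 1L]] <- data.frame(
      specimen_id = id, patient_id = s$patient_id[1L], layer = s$layer[1L],
      protocol = s$protocol[1L], final_state = fin_state,
      strain_inner_pct = e_in$strain_pct, strain_outer_pct = e_out$strain_pct,
      membrane_pct = dec$membrane_pct, bending_pct = dec$bending_pct,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

.parameter_cols <- c(thickness = "thickness_mean", opening_angle = "phi_deg",
                     inner_curvature = "kappa_in",
                     outer_curvature = "kappa_out",
                     inner_length = "length_in", outer_length = "length_out")

# per-layer protocol comparison over the six parameters, at the final state
.protocol_comparisons <- function(ps, layer, alpha) {
  res <- list()
  for (pname in names(.parameter_cols)) {
    col <- .parameter_cols[[pname]]
    vals <- lapply(c(1L, 2L), function(pr) {
      fin <- .final_state(pr, layer)
      v <- ps[ps$layer == layer & ps$protocol == pr &
                ps$time_state == fin, col]
      v[is.finite(v)]
    })
    res[[pname]] <- tryCatch(
      compare_independent(vals[[1L]], vals[[2L]],
                          label = sprintf("%s %s: protocol 1 vs 2",
                                          layer, pname),
                          alpha = alpha),
      error = function(e) NULL)
  }
  res[!vapply(res, is.null, logical(1))]
}

.summary_table <- function(ps, digits, alpha, by_protocol = FALSE) {
  cols <- c(opening_angle = "phi_deg", inner_curvature = "kappa_in",
            outer_curvature = "kappa_out", inner_length = "length_in",
            outer_length = "length_out")
  keys <- unique(ps[, c("layer", "time_state",
                        if (by_protocol) "protocol")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- ps$layer == keys$layer[i] & ps$time_state == keys$time_state[i]
    if (by_protocol) sel <- sel & ps$protocol == keys$protocol[i]
    s <- ps[sel, , drop = FALSE]
    row <- list(layer = keys$layer[i], time_state = keys$time_state[i],
                n = nrow(s))
    if (by_protocol) row$protocol <- keys$protocol[i]
    for (pname in names(cols)) {
      v <- s[[cols[[pname]]]]
      v <- v[is.finite(v)]
      row[[pname]] <- if (length(v) == 0L) "-" else
        as.character(summarize_sample(v, digits = digits, alpha = alpha))
      row[[paste0(pname, "_mean")]] <- if (length(v) == 0L) NA_real_
                                       else mean(v)
    }
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ord <- order(match(out$layer, c("I", "MI", "A")),
               match(out$time_state, names(.state_times)))
  out[ord, , drop = FALSE]
}

#' Run the full residual-deformation analysis pipeline
#'
#' Trace ingestion, scaling, geometry (curvature, length, opening angle per
#' specimen and time state), morphometry (thickness, A%, strains), and the
#' gated statistics: protocol comparisons with the merge decision, a
#' published-table-style cohort summary keyed by layer and time state,
#' paired ring-vs-final length tests, and the A% correlations for the
#' adventitia. Fully deterministic given its inputs.
#'
#' @param config a [run_config()].
#' @return list with `per_specimen`, `strains`, `summary` (formatted cohort
#'   table), `stats` (protocol comparisons, merge decision, paired length
#'   tests, A% correlations), `merge` (the merge decision actually applied)
#'   and `log` (character vector). Written to `out_dir` when configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  logf <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  rep <- validate_inputs(config$traces, config$metadata)
  if (nrow(rep$problems) > 0L) {
    fatal <- is.na(rep$problems$specimen_id)
    for (i in seq_len(nrow(rep$problems))) {
      logf("validation: %s [%s]", rep$problems$issue[i],
           rep$problems$specimen_id[i])
    }
    if (any(fatal)) {
      stop("input validation failed: ",
           paste(rep$problems$issue[fatal], collapse = "; "))
    }
  }
  tr <- read_traces(config$traces)
  meta <- read_metadata(config$metadata)
  if (nrow(tr) == 0L || length(meta$specimens) == 0L) {
    stop("empty input: no traces or no specimens")
  }

  ps <- .measure_all(tr, meta, config, logf)
  if (is.null(ps) || nrow(ps) == 0L) stop("no specimen could be measured")
  ps <- .fill_a_pct(ps)

  if (isTRUE(config$one_per_patient)) {
    keep_ids <- unlist(lapply(
      split(ps$specimen_id, paste(ps$patient_id, ps$layer)),
      function(x) sort(unique(x))[1L]))
    ps <- ps[ps$specimen_id %in% keep_ids, , drop = FALSE]
    logf("one-per-patient subsetting: %d specimens kept",
         length(unique(ps$specimen_id)))
  }

  strains <- .strain_table(ps, logf)

  # protocol merge decision, per layer over the six parameters
  comparisons <- list()
  merge_by_layer <- list()
  for (ly in intersect(c("MI", "A"), unique(ps$layer))) {
    if (length(unique(ps$protocol[ps$layer == ly])) == 2L) {
      cmp <- .protocol_comparisons(ps, ly, config$alpha)
      if (isTRUE(config$holm)) cmp <- holm_adjust(cmp)
      comparisons[[ly]] <- cmp
      merge_by_layer[[ly]] <- tryCatch(protocol_merge_decision(cmp),
                                       error = function(e) {
                                         logf("merge decision for %s: %s",
                                              ly, conditionMessage(e))
                                         NULL
                                       })
    }
  }
  decided <- Filter(Negate(is.null), merge_by_layer)
  merge_auto <- length(decided) > 0L &&
    all(vapply(decided, function(m) m$merge, logical(1)))
  merge <- switch(as.character(config$merge_protocols),
                  auto = merge_auto,
                  `TRUE` = TRUE, `FALSE` = FALSE, merge_auto)
  logf("protocol merge decision: %s",
       if (merge) "merged" else "kept separate")

  summary_tab <- .summary_table(ps, config$digits, config$alpha,
                                by_protocol = !merge)

  # paired ring-vs-final length comparisons per layer and boundary
  paired <- list()
  if (!is.null(strains)) {
    for (ly in unique(ps$layer)) {
      for (border in c("inner", "outer")) {
        col <- paste0("length_", if (border == "inner") "in" else "out")
        a <- c(); b <- c()
        for (id in unique(ps$specimen_id[ps$layer == ly])) {
          s <- ps[ps$specimen_id == id, , drop = FALSE]
          fin <- .final_state(s$protocol[1L], ly)
          r <- s[s$time_state == "ring", col]
          f <- s[s$time_state == fin, col]
          if (length(r) == 1L && length(f) == 1L) {
            a[id] <- r; b[id] <- f
          }
        }
        paired[[paste(ly, border, sep = "_")]] <- tryCatch(
          compare_paired(a, b, label = sprintf(
            "%s %s length: ring vs final", ly, border),
            alpha = config$alpha),
          error = function(e) NULL)
      }
    }
    paired <- Filter(Negate(is.null), paired)
  }

  # imperfect-separation correlations on the adventitia final state
  correlations <- list()
  afin <- ps[ps$layer == "A" &
               ps$time_state == mapply(.final_state, ps$protocol,
                                       ps$layer), , drop = FALSE]
  if (nrow(afin) >= 5L && any(is.finite(afin$a_pct))) {
    correlations$a_pct_vs_kappa_in <- tryCatch(
      spearman_correlation(afin$a_pct, afin$kappa_in,
                           label = "A% vs adventitia inner curvature",
                           alpha = config$alpha),
      error = function(e) NULL)
    correlations$a_pct_vs_phi <- tryCatch(
      spearman_correlation(afin$a_pct, afin$phi_deg,
                           label = "A% vs adventitia opening angle",
                           alpha = config$alpha),
      error = function(e) NULL)
    correlations <- Filter(Negate(is.null), correlations)
  }

  result <- list(per_specimen = ps, strains = strains,
                 summary = summary_tab,
                 stats = list(protocol_comparisons = comparisons,
                              merge_by_layer = decided,
                              paired_lengths = paired,
                              correlations = correlations),
                 merge = merge, log = log)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(ps, file.path(config$out_dir, "per_specimen.csv"),
              row.names = FALSE)
    if (!is.null(strains)) {
      write.csv(strains, file.path(config$out_dir, "strains.csv"),
                row.names = FALSE)
    }
    write.csv(summary_tab, file.path(config$out_dir, "summary.csv"),
              row.names = FALSE)
    stats_json <- list(
      merge = merge,
      protocol_p_values = lapply(comparisons, function(cmp)
        lapply(cmp, function(r) r$p_value)),
      paired_lengths = lapply(paired, function(r)
        list(test = r$test_used, p = r$p_value)),
      correlations = lapply(correlations, function(r)
        list(rho = r$rho, p = r$p_value)))
    jsonlite::write_json(stats_json,
                         file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log, file.path(config$out_dir, "log.txt"))
  }
  result
}
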