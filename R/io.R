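#' Write simulated or measured traces as delimited text
#'
#' Serializes an experiment's traces in the package's CSV dialect: header
#' row mandatory, comma-delimited, decimal point, concentrations in uM.
#' Signal experiments use columns \code{experiment_id, trace_id,
#' ligand_conc_uM, time_s, value}; quench experiments replace
#' \code{value} with \code{species, conc_uM} pairs (one row per species
#' per time).
#'
#' @param experiment an [experiment_spec()] with data attached, or a
#'   data.frame already in the trace-table shape.
#' @param path output file path.
#' @param experiment_id identifier written to the first column.
#' @return the written data.frame, invisibly.
#' @export
write_trace_csv <- function(experiment, path, experiment_id = "exp1") {
  df <- if (is.data.frame(experiment)) experiment else
    trace_table(experiment, experiment_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

## Flatten an experiment_spec's traces into the trace-table shape.
trace_table <- function(e, experiment_id = "exp1") {
  rows <- lapply(e$traces, function(tr) {
    lig <- if (!is.null(tr$ligand_conc)) sum(tr$ligand_conc) else NA_real_
    if (e$kind == "quench") {
      dat <- tr$data
      do.call(rbind, lapply(colnames(dat), function(sp)
        data.frame(experiment_id = experiment_id, trace_id = tr$trace_id,
                   ligand_conc_uM = lig, time_s = tr$times,
                   species = sp, conc_uM = dat[, sp])))
    } else if (e$kind == "titration") {
      data.frame(experiment_id = experiment_id, trace_id = tr$trace_id,
                 ligand_conc_uM = tr$titrant_total,
                 time_s = seq_along(tr$titrant_total) - 1,
                 value = as.numeric(tr$data))
    } else {
      data.frame(experiment_id = experiment_id, trace_id = tr$trace_id,
                 ligand_conc_uM = lig, time_s = tr$times,
                 value = as.numeric(tr$data))
    }
  })
  do.call(rbind, rows)
}

#' Read a trace table from delimited text
#'
#' Reads and validates the package's trace CSV dialect (see
#' [write_trace_csv()]).  Validation errors identify the offending column
#' or row.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- c("experiment_id", "trace_id", "ligand_conc_uM", "time_s")
  missing_base <- setdiff(base, names(df))
  if (length(missing_base))
    stop("missing column: ", paste(missing_base, collapse = ", "))
  if (!("value" %in% names(df)) &&
      !all(c("species", "conc_uM") %in% names(df)))
    stop("missing column: value (or species + conc_uM)")
  num_cols <- intersect(c("ligand_conc_uM", "time_s", "value", "conc_uM"),
                        names(df))
  for (cc in num_cols) {
    vals <- df[[cc]]
    if (!is.numeric(vals)) {
      suppressWarnings(conv <- as.numeric(vals))
      bad <- which(is.na(conv) & !is.na(vals) & vals != "NA")
      if (length(bad))
        stop("non-numeric value in column ", cc, " at data row ", bad[1L])
      df[[cc]] <- conv
    }
  }
  if (any(df$time_s < 0, na.rm = TRUE))
    stop("negative time at data row ", which(df$time_s < 0)[1L])
  key_cols <- intersect(c("trace_id", "species"), names(df))
  for (grp in split(seq_len(nrow(df)), df[key_cols], drop = TRUE)) {
    tt <- df$time_s[grp]
    if (any(diff(tt) < 0))
      stop("times not sorted within trace at data row ",
           grp[which(diff(tt) < 0)[1L] + 1L])
    if (anyDuplicated(tt))
      stop("duplicate time within trace at data row ",
           grp[which(duplicated(tt))[1L]])
  }
  df
}

#' Write a scheme and parameters as a YAML config
#'
#' The config schema (see \code{inst/schema/scheme-config.md}) has blocks
#' \code{name}, \code{states}, \code{ligands}, \code{transitions} (each
#' with \code{from}, \code{to}, \code{k_fwd} and optional \code{k_rev},
#' \code{ligand}, \code{ligand_rev}) and \code{parameters} (each with
#' \code{value}, \code{units}, and optional \code{locked}, \code{bounds},
#' \code{link_group}).
#'
#' @param scheme a [kinetic_scheme()].
#' @param params a [parameter_set()].
#' @param path output file path.
#' @export
write_scheme_config <- function(scheme, params, path) {
  tr <- scheme$transitions
  trans <- lapply(seq_len(nrow(tr)), function(i) {
    x <- list(from = tr$from[i], to = tr$to[i], k_fwd = tr$kf[i])
    if (!is.na(tr$kr[i])) x$k_rev <- tr$kr[i]
    if (!is.na(tr$ligand_f[i])) x$ligand <- tr$ligand_f[i]
    if (!is.na(tr$ligand_r[i])) x$ligand_rev <- tr$ligand_r[i]
    x
  })
  pars <- lapply(seq_len(nrow(params)), function(i) {
    x <- list(value = params$value[i], units = params$units[i])
    if (params$locked[i]) x$locked <- TRUE
    if (!is.na(params$lower[i]) || !is.na(params$upper[i]))
      x$bounds <- c(params$lower[i], params$upper[i])
    if (!is.na(params$link_group[i])) x$link_group <- params$link_group[i]
    x
  })
  names(pars) <- params$name
  yaml::write_yaml(list(name = scheme$name,
                        states = as.list(scheme$states),
                        ligands = as.list(scheme$ligands),
                        transitions = trans,
                        parameters = pars),
                   path)
  invisible(path)
}

#' Read a scheme and parameters from a YAML config
#'
#' @param path config file path (schema in
#'   \code{inst/schema/scheme-config.md}).  Parameter units may be given
#'   in \code{/mM/s} or \code{/nM/s}; values are converted to the internal
#'   uM/s convention on load.
#' @return list with elements \code{scheme} and \code{params}.
#' @export
read_scheme_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (block in c("name", "states", "transitions", "parameters"))
    if (is.null(cfg[[block]])) stop("config missing block: ", block)
  tr <- do.call(rbind, lapply(cfg$transitions, function(x) {
    if (is.null(x$from) || is.null(x$to) || is.null(x$k_fwd))
      stop("transition needs from, to, k_fwd")
    data.frame(from = x$from, to = x$to, kf = x$k_fwd,
               kr = x$k_rev %||% NA_character_,
               ligand_f = x$ligand %||% NA_character_,
               ligand_r = x$ligand_rev %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  scheme <- kinetic_scheme(cfg$name, unlist(cfg$states),
                           unlist(cfg$ligands) %||% character(), tr)
  pars <- lapply(cfg$parameters, function(x)
    list(value = x$value, units = x$units %||% "/s",
         locked = isTRUE(x$locked),
         lower = if (!is.null(x$bounds)) x$bounds[[1L]] else NA_real_,
         upper = if (!is.null(x$bounds)) x$bounds[[2L]] else NA_real_,
         link_group = x$link_group %||% NA_character_))
  params <- parameter_set(pars)
  check_scheme_params(scheme, params)
  list(scheme = scheme, params = params)
}

#' Export a contour scan as delimited text
#'
#' @param contour a [contour_scan()] result.
#' @param path output CSV path.
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(data.frame(parameter = contour$parameter,
                              grid_value = contour$grid,
                              ratio = contour$ratio),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
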