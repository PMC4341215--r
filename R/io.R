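curve_table_columns <- c("sample_id", "tissue_label", "probe_label",
                         "rinse_index", "time_min", "concentration_pM")

#' Tabulate dual-probe measurements
#'
#' Flattens a list of measurements into the canonical long table with one
#' row per sample x probe x rinse index (0-based; index 0 is the pre-rinse
#' measurement).
#'
#' @param measurements list of \code{\link{dual_probe_measurement}}.
#' @return A data frame with columns \code{sample_id}, \code{tissue_label},
#'   \code{probe_label}, \code{rinse_index}, \code{time_min},
#'   \code{concentration_pM}.
#' @export
curve_table <- function(measurements) {
  if (inherits(measurements, "dual_probe_measurement")) {
    measurements <- list(measurements)
  }
  rows <- lapply(measurements, function(m) {
    stopifnot(inherits(m, "dual_probe_measurement"))
    do.call(rbind, lapply(c("targeted", "untargeted"), function(p) {
      cv <- m[[p]]
      data.frame(sample_id = m$sample_id, tissue_label = m$tissue_label,
                 probe_label = p,
                 rinse_index = seq_along(cv$times) - 1L,
                 time_min = cv$times, concentration_pM = cv$values)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write dual-probe curves to CSV
#'
#' @param measurements list of \code{\link{dual_probe_measurement}} (or a
#'   curve table data frame).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_curves <- function(measurements, path) {
  tab <- if (is.data.frame(measurements)) measurements
         else curve_table(measurements)
  stopifnot(identical(names(tab), curve_table_columns))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read dual-probe curves from CSV
#'
#' Reads and validates the canonical long format (see
#' \code{\link{curve_table}}): the header must match exactly, every sample
#' must carry both probes on a shared, 0-based contiguous rinse index, and
#' times must be non-negative. Small negative concentrations (a known
#' artifact of spectral demultiplexing noise) are clamped to zero with a
#' warning.
#'
#' @param path CSV path.
#' @return List of \code{\link{dual_probe_measurement}}, in file order.
#' @export
read_curves <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(tab), curve_table_columns)) {
    stop("unexpected header: need exactly (",
         paste(curve_table_columns, collapse = ", "), ")", call. = FALSE)
  }
  if (any(tab$time_min < 0)) {
    stop("negative time_min at row ", which(tab$time_min < 0)[1L],
         call. = FALSE)
  }
  neg <- tab$concentration_pM < 0
  if (any(neg)) {
    warning(sum(neg), " negative concentration value(s) clamped to 0 ",
            "(first at row ", which(neg)[1L], ")", call. = FALSE)
    tab$concentration_pM[neg] <- 0
  }
  key <- paste(tab$sample_id, tab$probe_label, tab$rinse_index)
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, probe_label, rinse_index) at row ",
         which(duplicated(key))[1L], call. = FALSE)
  }
  out <- list()
  for (sid in unique(tab$sample_id)) {
    sub <- tab[tab$sample_id == sid, ]
    curves <- list()
    for (p in c("targeted", "untargeted")) {
      ps <- sub[sub$probe_label == p, ]
      if (nrow(ps) == 0L) {
        stop("sample '", sid, "' is missing its ", p, " probe rows",
             call. = FALSE)
      }
      ps <- ps[order(ps$rinse_index), ]
      if (!identical(as.integer(ps$rinse_index),
                     seq_len(nrow(ps)) - 1L)) {
        stop("sample '", sid, "' (", p, "): rinse_index must be ",
             "0-based and contiguous", call. = FALSE)
      }
      curves[[p]] <- concentration_curve(p, ps$time_min,
                                         ps$concentration_pM)
    }
    out[[length(out) + 1L]] <-
      dual_probe_measurement(sid, sub$tissue_label[1L],
                             curves$targeted, curves$untargeted)
  }
  out
}

#' Generate a synthetic tissue cohort
#'
#' Simulates the standard 26-sample study layout: 9 healthy-like samples
#' at the near-null BP, 8 moderate-expression samples at BP 1 and 9
#' high-expression samples at BP 3, all sharing the nonspecific binding
#' rates and measurement noise of the simulation defaults. Seeded and
#' reproducible.
#'
#' @param config a \code{\link{simulation_config}}; \code{bp_levels} must
#'   have 3 entries (low/moderate/high).
#' @param n_per_group samples per group, default \code{c(9, 8, 9)}.
#' @param tissue_labels group labels, default
#'   \code{c("healthy", "U251", "A431")}.
#' @param as_table return the flat \code{\link{curve_table}} (default)
#'   rather than the list of measurements.
#' @return A curve table data frame (or list of measurements).
#' @export
generate_cohort <- function(config = simulation_config(),
                            n_per_group = c(9L, 8L, 9L),
                            tissue_labels = c("healthy", "U251", "A431"),
                            as_table = TRUE) {
  stopifnot(inherits(config, "simulation_config"),
            length(config$bp_levels) == length(n_per_group),
            length(tissue_labels) == length(n_per_group))
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max - 1L,
                                sum(n_per_group)))
  ms <- list()
  k <- 0L
  for (g in seq_along(n_per_group)) {
    r <- rate_constants(F = config$F_washout,
                        k3 = config$bp_levels[g] * config$k4,
                        k4 = config$k4, k5 = config$k5_default,
                        k6 = config$k6)
    for (i in seq_len(n_per_group[g])) {
      k <- k + 1L
      ms[[k]] <- simulate_dual_probe(
        r, config$schedule, config$noise_percent, seed = seeds[k],
        sample_id = sprintf("%s_%02d", tissue_labels[g], i),
        tissue_label = tissue_labels[g])
    }
  }
  if (as_table) curve_table(ms) else ms
}

#' Run configuration from a flat key-value file
#'
#' Reads \code{key = value} lines (comments with \code{#}; unknown keys
#' rejected) into a \code{\link{simulation_config}} plus schedule fields.
#' Recognized keys: \code{stain_duration}, \code{rinse_interval},
#' \code{n_rinses}, \code{include_pre_rinse}, plus every scalar field of
#' \code{\link{simulation_config}} and comma-separated \code{bp_levels} /
#' \code{k5_sweep}.
#'
#' @param path configuration file path.
#' @return A \code{\link{simulation_config}}.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("malformed config line: '", lines[bad][1L], "'", call. = FALSE)
  }
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, `[[`, character(1), 2L)
  sched_keys <- c("stain_duration", "rinse_interval", "n_rinses",
                  "include_pre_rinse")
  num_keys <- c("bp_fixed_for_sweep", "k6", "k5_default", "k4",
                "F_washout", "noise_percent", "n_iterations", "seed")
  vec_keys <- c("bp_levels", "k5_sweep")
  known <- c(sched_keys, num_keys, vec_keys)
  if (any(!keys %in% known)) {
    stop("unknown config key: '", keys[!keys %in% known][1L], "'",
         call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop("duplicate config key: '", keys[duplicated(keys)][1L], "'",
         call. = FALSE)
  }
  sch_args <- list()
  cfg_args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    v <- vals[i]
    if (k == "include_pre_rinse") {
      sch_args[[k]] <- toupper(v) %in% c("TRUE", "1", "YES")
    } else if (k %in% sched_keys) {
      sch_args[[k]] <- as.numeric(v)
    } else if (k %in% vec_keys) {
      cfg_args[[k]] <- as.numeric(strsplit(v, ",")[[1L]])
    } else {
      cfg_args[[k]] <- as.numeric(v)
    }
  }
  cfg_args$schedule <- do.call(acquisition_schedule, sch_args)
  do.call(simulation_config, cfg_args)
}
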