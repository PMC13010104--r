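#' Write / read a movement trial as CSV
#'
#' Comma-separated, '.' decimal, mandatory header, UTF-8; columns
#' `time, row_index, cx, cy, cz, ez, ey, ex, semi_a, semi_b`, one line per
#' section per sample. Values are written at 17 significant digits so that
#' finite values round-trip bit-exactly.
#'
#' @param trial a `movement_trial`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "movement_trial"))
  df <- trial$sections
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding =
              "UTF-8")
  invisible(path)
}

#' @rdname write_trial_csv
#' @param sample_rate optional Hz override (inferred from timestamps).
#' @param label optional class tag.
#' @export
read_trial_csv <- function(path, sample_rate = NULL, label = NULL) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  movement_trial(df, sample_rate = sample_rate, label = label)
}

#' Write / read a movement trial as JSON
#'
#' JSON mirror of the CSV dialect: the section table plus the sample rate
#' and label.
#'
#' @param trial a `movement_trial`.
#' @param path file path.
#' @return `path` invisibly / a `movement_trial`.
#' @export
write_trial_json <- function(trial, path) {
  stopifnot(inherits(trial, "movement_trial"))
  jsonlite::write_json(list(sample_rate = trial$sample_rate,
                            label = trial$label,
                            sections = trial$sections),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trial_json
#' @export
read_trial_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  movement_trial(obj$sections, sample_rate = obj$sample_rate,
                 label = obj$label)
}

#' Read a marker table
#'
#' CSV with columns `time, row_index, marker_id, x, y, z`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_marker_csv <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  need <- c("time", "row_index", "marker_id", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("marker table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Fit a movement trial from a marker table
#'
#' Fits every section's ellipse per time sample via
#' [fit_section_ellipse()] and assembles a `movement_trial`.
#'
#' @param markers data.frame as from [read_marker_csv()].
#' @param sample_rate optional Hz.
#' @return A `movement_trial`.
#' @export
trial_from_markers <- function(markers, sample_rate = NULL) {
  times <- sort(unique(markers$time))
  rows <- sort(unique(markers$row_index))
  out <- vector("list", length(times) * length(rows))
  k <- 0L
  for (tt in times) {
    for (r in rows) {
      pts <- as.matrix(markers[markers$time == tt &
                                 markers$row_index == r,
                               c("x", "y", "z")])
      sec <- fit_section_ellipse(pts, row_index = r, timestamp = tt)
      k <- k + 1L
      out[[k]] <- data.frame(time = tt, row_index = r,
                             cx = sec$center[1], cy = sec$center[2],
                             cz = sec$center[3],
                             ez = sec$euler_zyx[1], ey = sec$euler_zyx[2],
                             ex = sec$euler_zyx[3],
                             semi_a = sec$semi_axes[1],
                             semi_b = sec$semi_axes[2])
    }
  }
  movement_trial(do.call(rbind, out), sample_rate = sample_rate)
}

#' Serialize / load a trunk structure as JSON
#'
#' @param structure a `trunk_structure`.
#' @param path file path.
#' @return `path` invisibly / a `trunk_structure`.
#' @export
write_structure_json <- function(structure, path) {
  stopifnot(inherits(structure, "trunk_structure"))
  jsonlite::write_json(list(
    nodes = structure$nodes, rods = structure$rods,
    fixed_nodes = structure$fixed_nodes,
    n_sections = structure$n_sections,
    segment_length = structure$segment_length,
    section_radii = structure$section_radii,
    config = unclass(structure$config)), path, auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}

#' @rdname write_structure_json
#' @export
read_structure_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(
    nodes = obj$nodes, rods = obj$rods, fixed_nodes = obj$fixed_nodes,
    n_sections = obj$n_sections, n_nodes = nrow(obj$nodes),
    segment_length = obj$segment_length,
    section_radii = obj$section_radii,
    config = validate_config(obj$config)), class = "trunk_structure")
}

#' Write a node trajectory as long CSV
#'
#' Columns `time, node_id, x, y, z` (node ids 0-based, matching the
#' structure).
#'
#' @param trajectory a `node_trajectory`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  nt <- length(trajectory$times)
  n_nodes <- dim(trajectory$positions)[2]
  df <- do.call(rbind, lapply(seq_len(nt), function(s) {
    data.frame(time = trajectory$times[s], node_id = 0:(n_nodes - 1L),
               x = trajectory$positions[s, , 1],
               y = trajectory$positions[s, , 2],
               z = trajectory$positions[s, , 3])
  }))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a force history as CSV
#'
#' Columns `time, segment, FR, FL_dorsal, FL_ventral, dFL, FmL`.
#'
#' @param history an `active_force_history` or its `history` data.frame.
#' @param path file path.
#' @return `path` invisibly / a data.frame.
#' @export
write_forces_csv <- function(history, path) {
  h <- if (inherits(history, "active_force_history")) history$history else
    history
  s <- segment_force_summary(h)
  df <- data.frame(time = h$time, segment = h$segment, FR = h$FR,
                   FL_dorsal = h$FL_dorsal, FL_ventral = h$FL_ventral,
                   dFL = s$dFL, FmL = s$FmL)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_forces_csv
#' @export
read_forces_csv <- function(path) {
  read.csv(path, fileEncoding = "UTF-8")
}

#' Serialize / load a law set as JSON
#'
#' Segment-indexed coefficient blocks with their fit statistics.
#'
#' @param laws a `law_set`.
#' @param path file path.
#' @return `path` invisibly / a `law_set`.
#' @export
write_laws_json <- function(laws, path) {
  stopifnot(inherits(laws, "law_set"))
  payload <- list(movement_class = laws$movement_class,
                  segments = laws$segments,
                  laws = lapply(laws$laws, function(lw) {
                    lapply(lw, function(cf) {
                      list(beta = as.list(cf$beta), r2 = cf$r2,
                           r2_adj = cf$r2_adj, rmse = cf$rmse,
                           residual_sd = cf$residual_sd,
                           n_samples = cf$n_samples)
                    })
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_laws_json
#' @export
read_laws_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  laws <- lapply(obj$laws, function(lw) {
    lapply(lw, function(cf) {
      structure(list(beta = unlist(cf$beta), r2 = cf$r2,
                     r2_adj = cf$r2_adj, rmse = cf$rmse,
                     residual_sd = cf$residual_sd,
                     n_samples = cf$n_samples),
                class = "law_coefficients")
    })
  })
  structure(list(laws = laws, segments = unlist(obj$segments),
                 n_segments = length(laws),
                 movement_class = obj$movement_class),
            class = "law_set")
}

#' Load a trial from a local copy of the deposited dataset
#'
#' Maps a locally downloaded deposit directory (or single file) into a
#' `movement_trial`. The loader is written against the documented fixture
#' layout (the trial CSV dialect of [write_trial_csv()], possibly in
#' millimeters/degrees) and normalizes units to meters and radians; it
#' never downloads anything itself.
#'
#' @param path file, or directory containing exactly one `*.csv`.
#' @param length_unit `"m"` or `"mm"`.
#' @param angle_unit `"rad"` or `"deg"`.
#' @param n_rows expected number of section rows (default 10).
#' @return A `movement_trial`.
#' @export
load_deposited_trial <- function(path, length_unit = c("m", "mm"),
                                 angle_unit = c("rad", "deg"),
                                 n_rows = 10L) {
  length_unit <- match.arg(length_unit)
  angle_unit <- match.arg(angle_unit)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) != 1) {
      stop("expected exactly one CSV in ", path, ", found ", length(files))
    }
    path <- files[1]
  }
  df <- read.csv(path, fileEncoding = "UTF-8")
  need <- c("time", "row_index", "cx", "cy", "cz", "ez", "ey", "ex",
            "semi_a", "semi_b")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("deposited trial is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (length(unique(df$row_index)) != n_rows) {
    stop("deposited trial has ", length(unique(df$row_index)),
         " section rows, expected ", n_rows)
  }
  if (length_unit == "mm") {
    for (cc in c("cx", "cy", "cz", "semi_a", "semi_b")) {
      df[[cc]] <- df[[cc]] / 1000
    }
  }
  if (angle_unit == "deg") {
    for (cc in c("ez", "ey", "ex")) df[[cc]] <- df[[cc]] * pi / 180
  }
  movement_trial(df)
}
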