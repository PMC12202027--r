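# Plain-text trajectory exchange format.
#
# TSV dialect: header row `frame<TAB><label>_x<TAB><label>_y<TAB><label>_z ...`
# with labels in sorted order, one row per frame, empty cells for missing
# samples, UTF-8, LF line endings, 6 decimal places. Trial metadata (task,
# frame rate, known pairs, surface-marker labels, residuals) travels in a
# YAML sidecar.

#' Write a trial to the TSV exchange format
#'
#' Columns are emitted in sorted label order and values with 6 decimal
#' places, so writing is deterministic and read/write round-trips are stable.
#' Missing frames become empty cells.
#'
#' @param trial a [trial_recording()].
#' @param path output TSV path.
#' @param meta_path optional path for the YAML metadata sidecar (task, frame
#'   rate, known pairs, surface labels, residuals).
#' @return invisibly, `path`.
#' @export
write_trial <- function(trial, path, meta_path = NULL) {
  stopifnot(inherits(trial, "trial_recording"))
  all_traj <- c(trial$markers, trial$surface_markers)
  labels <- sort(names(all_traj))
  nf <- trial_frames(trial)
  header <- "frame"
  cols <- list(format(seq_len(nf) - 1L))
  for (lab in labels) {
    header <- c(header, paste0(lab, "_", c("x", "y", "z")))
    m <- unclass(all_traj[[lab]])
    for (k in 1:3) {
      v <- sprintf("%.6f", m[, k])
      v[!is.finite(m[, k])] <- ""
      cols <- c(cols, list(v))
    }
  }
  lines <- c(
    paste(header, collapse = "\t"),
    if (nf > 0) do.call(paste, c(cols, sep = "\t"))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  if (!is.null(meta_path)) {
    meta <- list(
      trial_id = trial$trial_id, task = trial$task,
      frame_rate = trial$frame_rate,
      surface_labels = as.list(names(trial$surface_markers))
    )
    if (!is.null(trial$known_pairs)) {
      meta$known_pairs <- lapply(seq_len(nrow(trial$known_pairs)), function(i) {
        list(
          label_a = trial$known_pairs$label_a[i],
          label_b = trial$known_pairs$label_b[i],
          known_distance = trial$known_pairs$known_distance[i]
        )
      })
    }
    if (!is.null(trial$residuals)) {
      meta$residuals <- lapply(trial$residuals, function(r) round(as.numeric(r), 6))
    }
    yaml::write_yaml(meta, meta_path)
  }
  invisible(path)
}

#' Read a trial from the TSV exchange format
#'
#' Empty cells are flagged missing (never zero-filled); a frame with any of
#' its three coordinates missing is treated as wholly missing for that
#' marker. Malformed files fail with the offending line number.
#'
#' @param path TSV path in the dialect written by [write_trial()].
#' @param meta either a list of metadata fields (`trial_id`, `task`,
#'   `frame_rate`, `known_pairs`, `surface_labels`, `residuals`) or NULL.
#' @param meta_path optional YAML sidecar path; fields in `meta` override it.
#' @return a [trial_recording()].
#' @export
read_trial <- function(path, meta = NULL, meta_path = NULL) {
  side <- if (!is.null(meta_path)) yaml::read_yaml(meta_path) else list()
  meta <- utils::modifyList(side, as.list(meta %||% list()))
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("parse error at line 1: empty file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "frame") stop("parse error at line 1: first column must be 'frame'")
  coord_cols <- header[-1]
  if (length(coord_cols) %% 3 != 0) {
    stop("parse error at line 1: marker columns must come in _x/_y/_z triplets")
  }
  labels <- character(0)
  for (i in seq(1, length(coord_cols), by = 3)) {
    trip <- coord_cols[i:(i + 2)]
    lab <- sub("_x$", "", trip[1])
    if (!identical(trip, paste0(lab, "_", c("x", "y", "z")))) {
      stop("parse error at line 1: malformed column triplet near '", trip[1], "'")
    }
    labels <- c(labels, lab)
  }
  if (anyDuplicated(labels)) stop("parse error at line 1: duplicate marker labels")
  nf <- length(lines) - 1L
  ncol_exp <- length(header)
  vals <- matrix(NA_real_, nrow = nf, ncol = length(coord_cols))
  if (nf > 0) {
    for (r in seq_len(nf)) {
      n_tabs <- lengths(regmatches(lines[r + 1L], gregexpr("\t", lines[r + 1L], fixed = TRUE)))
      if (n_tabs != ncol_exp - 1L) {
        stop(sprintf("parse error at line %d: expected %d columns, found %d",
                     r + 1L, ncol_exp, n_tabs + 1L))
      }
      cells <- strsplit(lines[r + 1L], "\t", fixed = TRUE)[[1]]
      # trailing empty cells are dropped by strsplit; pad them back
      length(cells) <- ncol_exp
      cells[is.na(cells)] <- ""
      body <- cells[-1]
      nonempty <- body != ""
      num <- suppressWarnings(as.numeric(body[nonempty]))
      if (anyNA(num)) {
        bad <- body[nonempty][which(is.na(num))[1]]
        stop(sprintf("parse error at line %d: non-numeric cell '%s'", r + 1L, bad))
      }
      vals[r, nonempty] <- num
    }
  }
  surface_labels <- unlist(meta$surface_labels %||% character(0))
  trajs <- stats::setNames(vector("list", length(labels)), labels)
  for (j in seq_along(labels)) {
    xyz <- vals[, (3 * j - 2):(3 * j), drop = FALSE]
    trajs[[j]] <- trajectory(xyz)
  }
  kp <- meta$known_pairs
  if (!is.null(kp) && !inherits(kp, "marker_pairs")) {
    kp <- marker_pairs(
      vapply(kp, `[[`, "", "label_a"),
      vapply(kp, `[[`, "", "label_b"),
      vapply(kp, function(p) as.numeric(p[["known_distance"]]), numeric(1))
    )
  }
  res <- meta$residuals
  if (!is.null(res)) res <- lapply(res, as.numeric)
  trial_recording(
    trial_id = meta$trial_id %||% sub("\\.tsv$", "", basename(path)),
    task = meta$task %||% "OF",
    frame_rate = meta$frame_rate %||% 300,
    markers = trajs[setdiff(labels, surface_labels)],
    surface_markers = trajs[intersect(labels, surface_labels)],
    known_pairs = kp,
    residuals = res
  )
}
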