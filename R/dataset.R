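#' One subject's ROI BOLD recording
#'
#' @param subject_id subject identifier.
#' @param site acquisition-site identifier.
#' @param group diagnostic group label.
#' @param data numeric matrix, time points x nodes; must be finite with
#'   >= 16 time points and >= 2 nodes.
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @return An object of class \code{roi_ts}.
#' @export
roi_time_series <- function(subject_id, site, group, data, tr_seconds) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop_field("data", sprintf("non-finite values for subject '%s'", subject_id))
  }
  if (ncol(data) < 2) stop_field("data", "need >= 2 nodes")
  if (nrow(data) < 16) stop_field("data", "need >= 16 time points")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    stop_field("tr_seconds", "must be > 0")
  }
  structure(
    list(subject_id = as.character(subject_id), site = as.character(site),
         group = as.character(group), data = unname(data),
         tr_seconds = tr_seconds),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %s  site=%s group=%s  %d x %d  TR=%gs\n",
              x$subject_id, x$site, x$group, nrow(x$data), ncol(x$data),
              x$tr_seconds))
  invisible(x)
}

#' A cohort of ROI recordings
#'
#' All recordings must share the same node count; groups must come from the
#' configured label set.
#'
#' @param recordings list of \code{\link{roi_time_series}} objects.
#' @param node_names optional character vector naming the nodes.
#' @param groups allowed group labels.
#' @return An object of class \code{bold_cohort}.
#' @export
bold_cohort <- function(recordings, node_names = NULL,
                        groups = c("ASD", "APD", "PDD-NOS", "NC")) {
  if (!length(recordings)) stop_field("recordings", "empty cohort")
  if (!all(vapply(recordings, inherits, logical(1), "roi_ts"))) {
    stop_field("recordings", "all elements must be roi_ts")
  }
  ncols <- vapply(recordings, function(r) ncol(r$data), integer(1))
  if (length(unique(ncols)) != 1) {
    stop_field("recordings", sprintf("inconsistent node counts: %s",
                                     paste(unique(ncols), collapse = ", ")))
  }
  glabs <- vapply(recordings, function(r) r$group, character(1))
  bad <- setdiff(unique(glabs), groups)
  if (length(bad)) {
    stop_field("group", sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(node_names) && length(node_names) != ncols[1]) {
    stop_field("node_names", "length must equal node count")
  }
  structure(list(recordings = recordings, node_names = node_names,
                 groups = groups),
            class = "bold_cohort")
}

#' @export
print.bold_cohort <- function(x, ...) {
  glabs <- cohort_groups(x)
  tab <- table(factor(glabs, levels = x$groups))
  cat(sprintf("<bold_cohort> %d recordings, %d nodes\n",
              length(x$recordings), ncol(x$recordings[[1]]$data)))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

cohort_groups <- function(cohort) {
  vapply(cohort$recordings, function(r) r$group, character(1))
}

cohort_sites <- function(cohort) {
  vapply(cohort$recordings, function(r) r$site, character(1))
}

cohort_ids <- function(cohort) {
  vapply(cohort$recordings, function(r) r$subject_id, character(1))
}

#' Load a cohort from a manifest
#'
#' Reads the CSV manifest written by \code{\link{write_cohort}} and the
#' per-subject TSV time-series files it points to.
#'
#' @param manifest_path path to \code{manifest.csv}.
#' @param groups allowed group labels.
#' @return A \code{\link{bold_cohort}}.
#' @export
load_cohort <- function(manifest_path, groups = c("ASD", "APD", "PDD-NOS", "NC")) {
  if (!file.exists(manifest_path)) {
    stop(sprintf("manifest not found: '%s'", manifest_path), call. = FALSE)
  }
  man <- data.table::fread(manifest_path, data.table = FALSE)
  req <- c("subject_id", "site", "group", "tr_seconds", "n_timepoints", "file")
  if (!all(req %in% names(man))) {
    stop(sprintf("manifest missing columns: %s",
                 paste(setdiff(req, names(man)), collapse = ", ")), call. = FALSE)
  }
  dirn <- dirname(manifest_path)
  recs <- lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(dirn, man$file[i])
    if (!file.exists(path)) {
      stop(sprintf("time-series file missing for subject '%s': '%s'",
                   man$subject_id[i], path), call. = FALSE)
    }
    x <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE,
                                     data.table = FALSE))
    if (nrow(x) != man$n_timepoints[i]) {
      stop(sprintf("subject '%s': expected %d time points, found %d",
                   man$subject_id[i], man$n_timepoints[i], nrow(x)), call. = FALSE)
    }
    roi_time_series(man$subject_id[i], man$site[i], man$group[i], x,
                    man$tr_seconds[i])
  })
  bold_cohort(recs, groups = groups)
}

#' Truncate all recordings to the shortest common length
#'
#' Recording lengths vary across acquisition sites; all recordings are cut to
#' the minimum length present in the cohort, keeping the leading samples
#' (time index 1 onward). Idempotent, and retained samples are unaltered.
#'
#' @param cohort a \code{\link{bold_cohort}}.
#' @return A \code{bold_cohort} whose recordings all share the minimum length.
#' @export
truncate_to_common_length <- function(cohort) {
  stopifnot(inherits(cohort, "bold_cohort"))
  lens <- vapply(cohort$recordings, function(r) nrow(r$data), integer(1))
  tmin <- min(lens)
  recs <- lapply(cohort$recordings, function(r) {
    if (nrow(r$data) > tmin) r$data <- r$data[seq_len(tmin), , drop = FALSE]
    r
  })
  bold_cohort(recs, node_names = cohort$node_names, groups = cohort$groups)
}

#' Downsample groups to a common balanced size
#'
#' Each group is downsampled uniformly at random, without replacement and with
#' a recorded seed, to the size of the smallest group. The relative order of
#' the retained subjects is preserved.
#'
#' @param cohort a \code{\link{bold_cohort}}; every configured group must be
#'   present.
#' @param seed integer seed controlling the selection.
#' @return A balanced \code{bold_cohort}.
#' @export
balance_groups <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "bold_cohort"))
  glabs <- cohort_groups(cohort)
  missing <- setdiff(cohort$groups, unique(glabs))
  if (length(missing)) {
    stop(sprintf("group(s) absent from cohort: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sizes <- table(glabs)
  nmin <- min(sizes)
  set.seed(as.integer(seed))
  keep <- unlist(lapply(cohort$groups, function(g) {
    idx <- which(glabs == g)
    sort(sample(idx, nmin))
  }))
  keep <- sort(keep)  # preserve original relative order
  bold_cohort(cohort$recordings[keep], node_names = cohort$node_names,
              groups = cohort$groups)
}

#' Keep only the recordings of the given groups
#'
#' @param cohort a \code{\link{bold_cohort}}.
#' @param groups group labels to keep (becomes the cohort's configured set).
#' @return A \code{bold_cohort} restricted to \code{groups}.
#' @export
subset_groups <- function(cohort, groups) {
  stopifnot(inherits(cohort, "bold_cohort"))
  keep <- cohort_groups(cohort) %in% groups
  if (!any(keep)) stop("no recordings in the requested groups", call. = FALSE)
  bold_cohort(cohort$recordings[keep], node_names = cohort$node_names,
              groups = groups)
}
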