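#' Specification of a synthetic multi-site BOLD cohort
#'
#' Describes a cohort of BOLD-like ROI time series with planted, tunable group
#' effects: a spectral-power effect at one "planted" node and a phase-coupling
#' effect between the planted node and a set of partner nodes. Per-site linear
#' gain/offset distortions emulate scanner differences across acquisition
#' sites, which is what makes per-subject normalization in the node-ranking
#' stage consequential.
#'
#' Each node signal is a sum of three band-limited sinusoids with random
#' frequencies in the resting-state band 0.01-0.1 Hz and random phases, plus
#' white Gaussian noise. The planted node's oscillatory amplitude is multiplied
#' by the group's entry in \code{power_effects}; each partner node shares the
#' planted node's oscillatory component with mixing weight given by the group's
#' entry of \code{coupling_effects} (variance-preserving mixture
#' \eqn{c \cdot z + \sqrt{1-c^2} \cdot w} of the planted oscillation \eqn{z}
#' and an independent oscillation \eqn{w}).
#'
#' @param n_per_group subjects per diagnostic group (default 36, the balanced
#'   size of the emulated multi-site cohort).
#' @param groups ordered group labels; default \code{c("ASD","APD","PDD-NOS","NC")}.
#' @param n_nodes number of ROI nodes (default 116, AAL atlas size).
#' @param n_timepoints time points per recording (default 145).
#' @param tr_seconds repetition time / sampling interval in seconds (default 2).
#' @param sites data.frame with columns \code{site}, \code{n_subjects},
#'   \code{gain}, \code{offset}; \code{n_subjects} must sum to
#'   \code{n_per_group * length(groups)}. Default: four sites with distinct
#'   gains/offsets and near-even allocation.
#' @param planted_node index of the node carrying the group power effect.
#' @param partner_nodes indices of nodes phase-coupled to the planted node;
#'   default: the five nodes following \code{planted_node} (wrapping).
#' @param power_effects named numeric, one amplitude multiplier per group at
#'   the planted node. Defaults are ordered ASD > APD > PDD-NOS > NC,
#'   mirroring the observed ordering of spectral power across subtypes.
#' @param coupling_effects named numeric in [0,1], one phase-locking strength
#'   per group between planted and partner nodes.
#' @param noise_sd standard deviation of the additive white noise.
#' @param rng_seed master integer seed; per-subject streams are derived
#'   deterministically from (site, group, within-group index).
#'
#' @return An object of class \code{cohort_spec}.
#' @seealso \code{\link{generate_cohort}}
#' @export
cohort_spec <- function(n_per_group = 36,
                        groups = c("ASD", "APD", "PDD-NOS", "NC"),
                        n_nodes = 116,
                        n_timepoints = 145,
                        tr_seconds = 2.0,
                        sites = NULL,
                        planted_node = 30,
                        partner_nodes = NULL,
                        power_effects = c(ASD = 1.6, APD = 1.4, `PDD-NOS` = 1.2, NC = 1.0),
                        coupling_effects = c(ASD = 0.9, APD = 0.7, `PDD-NOS` = 0.5, NC = 0.3),
                        noise_sd = 1.0,
                        rng_seed = 1L) {
  if (!is.numeric(n_per_group) || n_per_group < 1) {
    stop_field("n_per_group", "must be >= 1")
  }
  if (length(groups) < 2 || anyDuplicated(groups)) {
    stop_field("groups", "need >= 2 distinct group labels")
  }
  if (!is.numeric(n_nodes) || n_nodes < 2) stop_field("n_nodes", "must be >= 2")
  if (!is.numeric(n_timepoints) || n_timepoints < 16) {
    stop_field("n_timepoints", "must be >= 16")
  }
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    stop_field("tr_seconds", "must be > 0")
  }
  n_total <- n_per_group * length(groups)
  if (is.null(sites)) {
    n_sites <- 4L
    base <- n_total %/% n_sites
    alloc <- rep(base, n_sites)
    alloc[seq_len(n_total - base * n_sites)] <- base + 1L
    sites <- data.frame(
      site = paste0("SITE", seq_len(n_sites)),
      n_subjects = alloc,
      gain = c(1.0, 1.2, 0.9, 1.1),
      offset = c(0.0, 0.5, -0.3, 0.2),
      stringsAsFactors = FALSE
    )
  }
  req <- c("site", "n_subjects", "gain", "offset")
  if (!is.data.frame(sites) || !all(req %in% names(sites))) {
    stop_field("sites", "must be a data.frame with columns site, n_subjects, gain, offset")
  }
  if (sum(sites$n_subjects) != n_total) {
    stop_field("sites", sprintf(
      "site allocations sum to %d but cohort has %d subjects",
      sum(sites$n_subjects), n_total
    ))
  }
  if (planted_node < 1 || planted_node > n_nodes) {
    stop_field("planted_node", "out of node range")
  }
  if (is.null(partner_nodes)) {
    partner_nodes <- ((planted_node + seq_len(min(5L, n_nodes - 1L)) - 1L) %% n_nodes) + 1L
  }
  partner_nodes <- setdiff(as.integer(partner_nodes), as.integer(planted_node))
  if (any(partner_nodes < 1 | partner_nodes > n_nodes)) {
    stop_field("partner_nodes", "out of node range")
  }
  for (nm in c("power_effects", "coupling_effects")) {
    eff <- get(nm)
    if (length(eff) != length(groups) || !all(groups %in% names(eff))) {
      stop_field(nm, "needs exactly one named entry per group")
    }
  }
  if (any(coupling_effects < 0 | coupling_effects > 1)) {
    stop_field("coupling_effects", "must lie in [0, 1]")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  structure(
    list(
      n_per_group = as.integer(n_per_group), groups = groups,
      n_nodes = as.integer(n_nodes), n_timepoints = as.integer(n_timepoints),
      tr_seconds = tr_seconds, sites = sites,
      planted_node = as.integer(planted_node),
      partner_nodes = as.integer(partner_nodes),
      power_effects = power_effects[groups],
      coupling_effects = coupling_effects[groups],
      noise_sd = noise_sd, rng_seed = as.integer(rng_seed)
    ),
    class = "cohort_spec"
  )
}

# deterministic per-subject seed derived from (master, site, group, index);
# kept below 2^31 so it is a valid R integer seed
subject_seed <- function(master, site_idx, group_idx, subj_idx) {
  s <- (as.double(master) * 2654435761 +
          site_idx * 40503 + group_idx * 65599 + subj_idx * 2946901) %% 2147483647
  as.integer(s)
}

#' Generate a synthetic multi-site BOLD cohort
#'
#' Draws one ROI time-series recording per subject according to a
#' \code{\link{cohort_spec}}. Identical spec and seed give bit-identical
#' output. Subjects are assigned to sites by cycling through the site table
#' (group-major subject order) while site capacity remains, so every site
#' receives a mixture of groups.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return A \code{\link{bold_cohort}} with
#'   \code{n_per_group * length(groups)} recordings, each an
#'   \code{n_timepoints x n_nodes} matrix.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_group = 2, n_nodes = 8,
#'                                       n_timepoints = 64))
#' length(cohort$recordings)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop_field("spec", "must be a cohort_spec")
  }
  n_groups <- length(spec$groups)
  n_total <- spec$n_per_group * n_groups
  # group-major subject table
  subj <- data.frame(
    group = rep(spec$groups, each = spec$n_per_group),
    group_idx = rep(seq_len(n_groups), each = spec$n_per_group),
    subj_idx = rep(seq_len(spec$n_per_group), times = n_groups),
    stringsAsFactors = FALSE
  )
  # cyclic site assignment under capacity
  remaining <- spec$sites$n_subjects
  site_of <- integer(n_total)
  s <- 1L
  for (i in seq_len(n_total)) {
    while (remaining[s] == 0L) s <- (s %% nrow(spec$sites)) + 1L
    site_of[i] <- s
    remaining[s] <- remaining[s] - 1L
    s <- (s %% nrow(spec$sites)) + 1L
  }
  subj$site_idx <- site_of
  subj$site <- spec$sites$site[site_of]

  tt <- (seq_len(spec$n_timepoints) - 1) * spec$tr_seconds
  recs <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    g <- subj$group[i]
    seed_i <- subject_seed(spec$rng_seed, subj$site_idx[i],
                           subj$group_idx[i], subj$subj_idx[i])
    set.seed(seed_i)
    n_osc <- 3L
    # frequencies/phases for every node, planted node first so that partner
    # coupling can reuse its oscillation
    freqs <- matrix(runif(n_osc * spec$n_nodes, 0.01, 0.1), n_osc, spec$n_nodes)
    phases <- matrix(runif(n_osc * spec$n_nodes, 0, 2 * pi), n_osc, spec$n_nodes)
    osc <- matrix(0, spec$n_timepoints, spec$n_nodes)
    for (j in seq_len(spec$n_nodes)) {
      osc[, j] <- rowSums(sin(outer(tt, 2 * pi * freqs[, j]) +
                                matrix(phases[, j], spec$n_timepoints, n_osc, byrow = TRUE)))
    }
    planted_osc <- osc[, spec$planted_node]
    # group power effect at the planted node
    osc[, spec$planted_node] <- planted_osc * spec$power_effects[[g]]
    # phase coupling of partner nodes to the planted oscillation
    cc <- spec$coupling_effects[[g]]
    for (j in spec$partner_nodes) {
      osc[, j] <- cc * planted_osc + sqrt(1 - cc^2) * osc[, j]
    }
    x <- osc + matrix(rnorm(spec$n_timepoints * spec$n_nodes, sd = spec$noise_sd),
                      spec$n_timepoints, spec$n_nodes)
    # site effect last: linear gain and offset
    x <- x * spec$sites$gain[subj$site_idx[i]] + spec$sites$offset[subj$site_idx[i]]
    recs[[i]] <- roi_time_series(
      subject_id = sprintf("%s_%s_%02d", subj$site[i], g, subj$subj_idx[i]),
      site = subj$site[i], group = g, data = x, tr_seconds = spec$tr_seconds
    )
  }
  bold_cohort(recs, groups = spec$groups)
}

#' Write a cohort to disk as TSV time series plus a CSV manifest
#'
#' One tab-separated file per subject (rows = time points, columns = nodes, no
#' header) and a \code{manifest.csv} with columns \code{subject_id}, \code{site},
#' \code{group}, \code{tr_seconds}, \code{n_timepoints}, \code{file}. Doubles
#' are written at full round-trip precision.
#'
#' @param cohort a \code{\link{bold_cohort}}.
#' @param directory output directory (created if missing).
#' @return The manifest path, invisibly usable with \code{\link{load_cohort}}.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "bold_cohort"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory '%s'", directory), call. = FALSE)
  }
  rows <- lapply(cohort$recordings, function(r) {
    fn <- paste0(r$subject_id, ".tsv")
    path <- file.path(directory, fn)
    # %.17g guarantees bit-exact double round-trip through the text file
    lines <- apply(r$data, 1, function(row) {
      paste(sprintf("%.17g", row), collapse = "\t")
    })
    writeLines(lines, path)
    data.frame(subject_id = r$subject_id, site = r$site, group = r$group,
               tr_seconds = r$tr_seconds, n_timepoints = nrow(r$data),
               file = fn, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(directory, "manifest.csv")
  data.table::fwrite(manifest, mpath)
  invisible(mpath)
}
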