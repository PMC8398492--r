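#' Welch estimator configuration
#'
#' Conventional defaults for short physiological series: 64-sample segments,
#' 50\% overlap, Hamming window, per-segment mean removal. A 145-point series
#' then yields three averaged segments.
#'
#' @param segment_length samples per segment.
#' @param overlap fractional overlap between consecutive segments in [0,1).
#' @param window window type, currently \code{"hamming"} or \code{"hann"}.
#' @param detrend per-segment detrending, \code{"mean"} or \code{"none"}.
#' @return An object of class \code{welch_config}.
#' @export
welch_config <- function(segment_length = 64L, overlap = 0.5,
                         window = c("hamming", "hann"),
                         detrend = c("mean", "none")) {
  window <- match.arg(window)
  detrend <- match.arg(detrend)
  if (segment_length < 8) stop_field("segment_length", "must be >= 8")
  if (overlap < 0 || overlap >= 1) stop_field("overlap", "must be in [0,1)")
  structure(list(segment_length = as.integer(segment_length), overlap = overlap,
                 window = window, detrend = detrend),
            class = "welch_config")
}

#' Welch power spectral density
#'
#' Averaged modified periodogram over overlapping windowed segments, one
#' spectrum per node (column). One-sided density scaling: power integrates to
#' approximately the signal variance.
#'
#' @param signal numeric vector or matrix (time points x nodes).
#' @param tr_seconds sampling interval in seconds.
#' @param config a \code{\link{welch_config}}.
#' @return An object of class \code{psd_estimate}: list with
#'   \code{frequencies} (Hz, length \code{nfft/2 + 1}, up to Nyquist
#'   \code{1/(2 tr_seconds)}) and \code{power} (nodes x frequencies,
#'   non-negative).
#' @export
welch_psd <- function(signal, tr_seconds, config = welch_config()) {
  x <- as.matrix(signal)
  n <- nrow(x)
  L <- config$segment_length
  if (n < L) {
    stop(sprintf("signal length %d shorter than segment length %d", n, L),
         call. = FALSE)
  }
  step <- max(1L, as.integer(round(L * (1 - config$overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- switch(config$window,
    hamming = as.numeric(signal::hamming(L)),
    hann = as.numeric(signal::hanning(L))
  )
  fs <- 1 / tr_seconds
  u <- sum(w^2)                       # window power normalization
  nf <- L %/% 2 + 1L
  freqs <- (seq_len(nf) - 1) * fs / L
  acc <- matrix(0, ncol(x), nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L), , drop = FALSE]
    if (config$detrend == "mean") {
      seg <- sweep(seg, 2, colMeans(seg))
    }
    seg <- seg * w
    ft <- stats::mvfft(seg)
    p <- (Mod(ft[seq_len(nf), , drop = FALSE])^2) / (fs * u)
    # one-sided: double all bins except DC (and Nyquist when L is even)
    dbl <- rep(2, nf)
    dbl[1] <- 1
    if (L %% 2 == 0) dbl[nf] <- 1
    acc <- acc + t(p * dbl)
  }
  structure(list(frequencies = freqs, power = acc / length(starts)),
            class = "psd_estimate")
}

#' Per-subject node scores from a PSD estimate
#'
#' All PSD values of one subject (nodes x retained frequencies) are jointly
#' z-scored to zero mean and unit standard deviation, then averaged over
#' frequency per node. The joint z-score removes per-site affine scale while
#' preserving between-node contrasts. The DC bin is excluded by default; a
#' frequency band (Hz) may restrict the average further.
#'
#' @param psd a \code{\link{welch_psd}} result for one subject.
#' @param band optional numeric length-2 frequency band in Hz; default: full
#'   grid excluding the DC bin.
#' @return Numeric vector of one score per node, in pooled SD units.
#' @export
summarize_psd <- function(psd, band = NULL) {
  stopifnot(inherits(psd, "psd_estimate"))
  keep <- psd$frequencies > 0
  if (!is.null(band)) {
    keep <- keep & psd$frequencies >= band[1] & psd$frequencies <= band[2]
    if (!any(keep)) stop_field("band", "no frequency bins inside band")
  }
  p <- psd$power[, keep, drop = FALSE]
  mu <- mean(p)
  sdv <- sd(as.vector(p))
  if (!is.finite(sdv) || sdv == 0) {
    stop("constant PSD (zero variance): node scores undefined for this subject",
         call. = FALSE)
  }
  rowMeans((p - mu) / sdv)
}

#' One-way fixed-effects ANOVA p-value
#'
#' Classic equal-variance one-way ANOVA: F on (k-1, N-k) degrees of freedom,
#' upper-tail p. Degenerate inputs with no variance at all (every observation
#' identical) return p = 1: such a node carries no group information.
#'
#' @param group_samples list of numeric vectors, one per group; >= 2 groups,
#'   each with >= 2 observations.
#' @return Named list with \code{f}, \code{p}, \code{df}.
#' @export
anova_pvalue <- function(group_samples) {
  if (length(group_samples) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(group_samples, length, integer(1)) < 2)) {
    stop("every group needs >= 2 observations", call. = FALSE)
  }
  y <- unlist(group_samples, use.names = FALSE)
  g <- factor(rep(seq_along(group_samples),
                  vapply(group_samples, length, integer(1))))
  k <- nlevels(g)
  dfs <- c(k - 1L, length(y) - k)
  if (all(y == y[1])) {
    return(list(f = 0, p = 1, df = dfs))
  }
  within_var <- tapply(y, g, stats::var)
  if (all(within_var == 0)) {
    # groups internally constant but group means differ: infinitely strong effect
    return(list(f = Inf, p = 0, df = dfs))
  }
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  f <- unname(ow$statistic)
  p <- unname(ow$p.value)
  if (!is.finite(p)) p <- 1
  list(f = f, p = p, df = dfs)
}

#' Rank nodes by group-discriminative spectral power
#'
#' For each subject, node scores are computed from the Welch PSD
#' (\code{\link{welch_psd}} then \code{\link{summarize_psd}}); for each node,
#' scores are compared across diagnostic groups by one-way ANOVA. Nodes with
#' p <= \code{alpha} form the significant list, sorted ascending by p with
#' ties broken by node index; the first is the top-ranked node used to seed
#' the wavelet-coherence stage.
#'
#' @param cohort a \code{\link{bold_cohort}} containing >= 2 groups.
#' @param alpha significance threshold on the raw p-value (default 0.05; no
#'   multiple-testing correction by default).
#' @param config a \code{\link{welch_config}}.
#' @param band optional frequency band (Hz) passed to
#'   \code{\link{summarize_psd}}.
#' @param bonferroni if TRUE, threshold at \code{alpha / n_nodes} instead.
#' @return An object of class \code{node_ranking}: list with \code{p_values}
#'   (one per node), \code{significant_nodes} (indices, sorted by p),
#'   \code{top_node} (NA when no node is significant), \code{alpha},
#'   \code{scores} (subjects x nodes matrix), \code{groups}.
#' @export
rank_nodes <- function(cohort, alpha = 0.05, config = welch_config(),
                       band = NULL, bonferroni = FALSE) {
  stopifnot(inherits(cohort, "bold_cohort"))
  glabs <- cohort_groups(cohort)
  if (length(unique(glabs)) < 2) {
    stop("cohort must contain >= 2 groups", call. = FALSE)
  }
  scores <- t(vapply(cohort$recordings, function(r) {
    summarize_psd(welch_psd(r$data, r$tr_seconds, config), band = band)
  }, numeric(ncol(cohort$recordings[[1]]$data))))
  n_nodes <- ncol(scores)
  thr <- if (bonferroni) alpha / n_nodes else alpha
  pv <- vapply(seq_len(n_nodes), function(j) {
    anova_pvalue(split(scores[, j], glabs))$p
  }, numeric(1))
  sig <- which(pv <= thr)
  sig <- sig[order(pv[sig], sig)]     # ascending p, ties -> lower node index
  structure(
    list(p_values = pv,
         significant_nodes = sig,
         top_node = if (length(sig)) sig[1] else NA_integer_,
         alpha = alpha, threshold = thr,
         scores = scores, groups = glabs,
         node_names = cohort$node_names),
    class = "node_ranking"
  )
}

#' @export
print.node_ranking <- function(x, ...) {
  cat(sprintf("<node_ranking> %d nodes, %d significant at p <= %g\n",
              length(x$p_values), length(x$significant_nodes), x$threshold))
  if (length(x$significant_nodes)) {
    top <- head(x$significant_nodes, 5)
    cat("  top nodes:", paste(sprintf("#%d (p=%.3g)", top, x$p_values[top]),
                              collapse = ", "), "\n")
  } else {
    cat("  no significant node (top_node undefined)\n")
  }
  invisible(x)
}

#' Write a node-ranking report as CSV
#'
#' One row per node: index, optional name, ANOVA p-value, and rank among the
#' significant nodes (NA if not significant).
#'
#' @param ranking a \code{\link{rank_nodes}} result.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_ranking_report <- function(ranking, path) {
  stopifnot(inherits(ranking, "node_ranking"))
  n <- length(ranking$p_values)
  rank <- rep(NA_integer_, n)
  rank[ranking$significant_nodes] <- seq_along(ranking$significant_nodes)
  df <- data.frame(
    node = seq_len(n),
    node_name = if (is.null(ranking$node_names)) NA_character_ else ranking$node_names,
    p_value = ranking$p_values,
    rank = rank
  )
  data.table::fwrite(df, path)
  invisible(path)
}
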