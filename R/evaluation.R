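#' Binary classification metrics from confusion counts
#'
#' Precision, sensitivity (recall), specificity, accuracy and F-score,
#' reported as percentages:
#' \deqn{P = TP/(TP+FP),\; Se = TP/(TP+FN),\; Sp = TN/(TN+FP),}
#' \deqn{Acc = (TP+TN)/(TP+TN+FP+FN),\; F = 2 P Se/(P+Se).}
#' A 0/0 ratio is reported as 0 and flagged in the \code{undefined} field.
#'
#' @param tp,fp,fn,tn non-negative integer counts; their total must be > 0.
#' @return Named list with the five metrics (percent) and \code{undefined},
#'   a character vector naming any metric with a zero denominator.
#' @export
binary_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(counts) == 0) stop("all counts are zero", call. = FALSE)
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(0)
    }
    100 * num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  sensitivity <- ratio(tp, tp + fn, "sensitivity")
  specificity <- ratio(tn, tn + fp, "specificity")
  accuracy <- 100 * (tp + tn) / sum(counts)
  f_score <- if (precision + sensitivity == 0) {
    undefined <- c(undefined, "f_score")
    0
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  list(precision = precision, sensitivity = sensitivity,
       specificity = specificity, accuracy = accuracy, f_score = f_score,
       undefined = undefined)
}

#' Confusion matrix from true and predicted labels
#'
#' @param truth,predicted label vectors of equal length.
#' @param classes class order (rows = truth, columns = predicted).
#' @return An object of class \code{confusion_matrix} (integer K x K matrix
#'   with a \code{classes} attribute).
#' @export
confusion_matrix <- function(truth, predicted, classes = sort(unique(c(truth, predicted)))) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length", call. = FALSE)
  }
  t_f <- factor(as.character(truth), levels = classes)
  p_f <- factor(as.character(predicted), levels = classes)
  if (anyNA(t_f) || anyNA(p_f)) stop("labels outside the class set", call. = FALSE)
  m <- unclass(table(t_f, p_f))
  dimnames(m) <- list(truth = classes, predicted = classes)
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Macro-averaged metrics of a multi-class confusion matrix
#'
#' Each class is binarized one-vs-rest; the five binary metrics are computed
#' per class and their unweighted mean across classes forms the macro row.
#' Classes with zero support (no true items) are flagged and, by default,
#' excluded from the averaging.
#'
#' @param confusion a \code{\link{confusion_matrix}} (or plain K x K matrix,
#'   rows = truth).
#' @param zero_support how to treat classes with no true items:
#'   \code{"exclude"} from the macro average (default) or score them as
#'   \code{"zero"}.
#' @return An object of class \code{metrics_report}: data.frame with one row
#'   per class plus a \code{"macro"} row; columns are the five metrics in
#'   percent. Zero-support classes are listed in the
#'   \code{"zero_support_classes"} attribute.
#' @export
macro_average <- function(confusion, zero_support = c("exclude", "zero")) {
  zero_support <- match.arg(zero_support)
  m <- unclass(confusion)
  if (nrow(m) != ncol(m) || nrow(m) < 2) stop("need a K x K matrix, K >= 2", call. = FALSE)
  classes <- rownames(m) %||% as.character(seq_len(nrow(m)))
  total <- sum(m)
  rows <- list()
  zero_classes <- character(0)
  for (k in seq_len(nrow(m))) {
    tp <- m[k, k]
    fn <- sum(m[k, ]) - tp
    fp <- sum(m[, k]) - tp
    tn <- total - tp - fn - fp
    if (tp + fn == 0) zero_classes <- c(zero_classes, classes[k])
    bm <- binary_metrics(tp, fp, fn, tn)
    rows[[k]] <- data.frame(class = classes[k], precision = bm$precision,
                            sensitivity = bm$sensitivity,
                            specificity = bm$specificity,
                            accuracy = bm$accuracy, f_score = bm$f_score)
  }
  per_class <- do.call(rbind, rows)
  avg_rows <- if (zero_support == "exclude") {
    per_class[!per_class$class %in% zero_classes, , drop = FALSE]
  } else {
    per_class
  }
  macro <- data.frame(class = "macro",
                      t(colMeans(avg_rows[, -1, drop = FALSE])))
  out <- rbind(per_class, macro)
  rownames(out) <- NULL
  attr(out, "zero_support_classes") <- zero_classes
  attr(out, "confusion") <- m
  class(out) <- c("metrics_report", class(out))
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  y <- as.data.frame(x)
  y[, -1] <- round(y[, -1], 1)   # one-decimal report convention
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

# largest-remainder allocation of n items to ratio shares
allocate_counts <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

split_items_frame <- function(items) {
  if (!is.data.frame(items) || !"class" %in% names(items)) {
    stop("items must be a data.frame with a `class` column", call. = FALSE)
  }
  items
}

#' Stratified train/validation/test hold-out split
#'
#' Splits items into train/validation/test sets stratified by class, with set
#' sizes within one item of the exact ratios per class. With
#' \code{unit = "subject"} all images of one subject stay in the same
#' partition (leakage guard); with the default \code{unit = "image"} a
#' subject's images may straddle partitions, which mirrors image-level
#' experimental counts but is optimistic for subject-level diagnosis — a
#' warning notes this when subject ids are present.
#'
#' @param items data.frame with a \code{class} column and, for subject-unit
#'   splits, a \code{subject_id} column.
#' @param ratios length-3 numeric summing to 1 (train, validation, test);
#'   default \code{c(0.7, 0.15, 0.15)}.
#' @param unit \code{"image"} or \code{"subject"}.
#' @param seed integer seed; identical seed gives an identical plan.
#' @return An object of class \code{split_plan} with integer index vectors
#'   \code{train}, \code{validation}, \code{test} (disjoint, covering).
#' @export
make_holdout_split <- function(items, ratios = c(0.7, 0.15, 0.15),
                               unit = c("image", "subject"), seed = 1L) {
  unit <- match.arg(unit)
  items <- split_items_frame(items)
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be three numbers summing to 1", call. = FALSE)
  }
  if (unit == "image" && "subject_id" %in% names(items) &&
      anyDuplicated(items$subject_id)) {
    warning("image-level split: images of one subject may straddle partitions",
            call. = FALSE)
  }
  set.seed(as.integer(seed))
  sets <- list(train = integer(0), validation = integer(0), test = integer(0))
  if (unit == "image") {
    for (cl in unique(items$class)) {
      idx <- sample(which(items$class == cl))
      counts <- allocate_counts(length(idx), ratios)
      sets$train <- c(sets$train, idx[seq_len(counts[1])])
      sets$validation <- c(sets$validation,
                           idx[counts[1] + seq_len(counts[2])])
      sets$test <- c(sets$test, idx[counts[1] + counts[2] + seq_len(counts[3])])
    }
  } else {
    if (!"subject_id" %in% names(items)) {
      stop("subject-unit split needs a `subject_id` column", call. = FALSE)
    }
    subj <- unique(items[, c("subject_id", "class")])
    if (anyDuplicated(subj$subject_id)) {
      stop("a subject appears with more than one class", call. = FALSE)
    }
    for (cl in unique(subj$class)) {
      ids <- sample(subj$subject_id[subj$class == cl])
      counts <- allocate_counts(length(ids), ratios)
      grp <- rep(c("train", "validation", "test"), counts)
      for (part in names(sets)) {
        sets[[part]] <- c(sets[[part]],
                          which(items$subject_id %in% ids[grp == part]))
      }
    }
  }
  structure(list(unit = unit, seed = as.integer(seed),
                 train = sort(sets$train), validation = sort(sets$validation),
                 test = sort(sets$test), n_items = nrow(items)),
            class = "split_plan")
}

#' Stratified k-fold cross-validation plan
#'
#' @param items data.frame with a \code{class} column (and \code{subject_id}
#'   for subject-unit folds).
#' @param k number of folds; must not exceed the size of any class (in the
#'   chosen unit).
#' @param unit \code{"image"} or \code{"subject"}.
#' @param seed integer seed.
#' @return An object of class \code{split_plan} with a \code{folds} list of k
#'   disjoint index vectors covering all items, stratified by class.
#' @export
kfold_plan <- function(items, k = 10L, unit = c("image", "subject"), seed = 1L) {
  unit <- match.arg(unit)
  items <- split_items_frame(items)
  k <- as.integer(k)
  if (k < 2 || k > nrow(items)) stop("k out of range", call. = FALSE)
  set.seed(as.integer(seed))
  folds <- vector("list", k)
  assign_units <- function(unit_ids, item_idx_of) {
    for (cl_ids in unit_ids) {
      if (length(cl_ids) < k) {
        stop(sprintf("class has %d units but k = %d", length(cl_ids), k),
             call. = FALSE)
      }
      ids <- sample(cl_ids)
      fold_of <- rep(seq_len(k), length.out = length(ids))
      for (f in seq_len(k)) {
        folds[[f]] <<- c(folds[[f]], item_idx_of(ids[fold_of == f]))
      }
    }
  }
  if (unit == "image") {
    assign_units(split(seq_len(nrow(items)), items$class), identity)
  } else {
    if (!"subject_id" %in% names(items)) {
      stop("subject-unit folds need a `subject_id` column", call. = FALSE)
    }
    subj <- unique(items[, c("subject_id", "class")])
    assign_units(split(subj$subject_id, subj$class),
                 function(ids) which(items$subject_id %in% ids))
  }
  folds <- lapply(folds, sort)
  structure(list(unit = unit, seed = as.integer(seed), k = k, folds = folds,
                 n_items = nrow(items)),
            class = "split_plan")
}

#' Leave-one-site-out cross-validation plan
#'
#' One hold-out round per eligible site: a site is an eligible test site only
#' if it contains every required class; ineligible sites never serve as test
#' sets but always remain in training.
#'
#' @param items data.frame with \code{site} and \code{class} columns.
#' @param required_classes classes a test site must contain; default: all
#'   classes present in \code{items}.
#' @return An object of class \code{split_plan} with a \code{rounds} list,
#'   each holding \code{site}, \code{train}, \code{test} index vectors.
#' @export
leave_one_site_out <- function(items, required_classes = NULL) {
  items <- split_items_frame(items)
  if (!"site" %in% names(items)) {
    stop("items must have a `site` column", call. = FALSE)
  }
  if (is.null(required_classes)) required_classes <- unique(items$class)
  sites <- unique(items$site)
  eligible <- sites[vapply(sites, function(s) {
    all(required_classes %in% items$class[items$site == s])
  }, logical(1))]
  if (!length(eligible)) {
    stop("no site contains all required classes", call. = FALSE)
  }
  rounds <- lapply(eligible, function(s) {
    list(site = s, test = which(items$site == s),
         train = which(items$site != s))
  })
  names(rounds) <- eligible
  structure(list(unit = "site", rounds = rounds, n_items = nrow(items),
                 eligible_sites = eligible),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  if (!is.null(x$folds)) {
    cat(sprintf("<split_plan> %d-fold (%s unit), %d items\n",
                x$k, x$unit, x$n_items))
  } else if (!is.null(x$rounds)) {
    cat(sprintf("<split_plan> leave-one-site-out, %d rounds: %s\n",
                length(x$rounds), paste(x$eligible_sites, collapse = ", ")))
  } else {
    cat(sprintf("<split_plan> holdout (%s unit): %d/%d/%d\n", x$unit,
                length(x$train), length(x$validation), length(x$test)))
  }
  invisible(x)
}

#' Format a metric as "mean ± SD" at one decimal
#'
#' @param values numeric vector of per-fold or per-site metric values.
#' @return Character scalar like \code{"86.8 ± 0.7"}.
#' @export
format_mean_sd <- function(values) {
  sprintf("%.1f ± %.1f", mean(values), sd(values))
}

#' Aggregate per-round metric rows into a mean ± SD report
#'
#' @param rows data.frame with one row per fold/site and numeric metric
#'   columns; a \code{round} id column is preserved.
#' @return data.frame with the input rows plus \code{"mean"} and \code{"sd"}
#'   rows, and a \code{"mean_sd"} attribute of formatted strings.
#' @export
aggregate_rounds <- function(rows) {
  num <- vapply(rows, is.numeric, logical(1))
  mrow <- rows[1, , drop = FALSE]
  srow <- rows[1, , drop = FALSE]
  mrow[!num] <- "mean"; srow[!num] <- "sd"
  mrow[num] <- as.list(colMeans(rows[, num, drop = FALSE]))
  srow[num] <- as.list(apply(rows[, num, drop = FALSE], 2, sd))
  out <- rbind(rows, mrow, srow)
  rownames(out) <- NULL
  attr(out, "mean_sd") <- vapply(which(num), function(j) {
    format_mean_sd(rows[[j]])
  }, character(1))
  out
}

#' Write a metrics report (and its confusion matrix) to CSV/JSON
#'
#' @param report a \code{\link{macro_average}} result or plain data.frame.
#' @param path_csv CSV output path.
#' @param path_json optional JSON output path.
#' @return \code{path_csv}, invisibly.
#' @export
write_metrics_report <- function(report, path_csv, path_json = NULL) {
  df <- as.data.frame(report)
  data.table::fwrite(df, path_csv)
  cm <- attr(report, "confusion")
  if (!is.null(cm)) {
    data.table::fwrite(as.data.frame(cm), sub("\\.csv$", "_confusion.csv", path_csv),
                       row.names = TRUE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(list(metrics = df, confusion = cm), path_json,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path_csv)
}
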