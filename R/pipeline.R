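#' Scalogram image bookkeeping
#'
#' With one seed node, a recording of \eqn{n} nodes yields \eqn{n-1} pairwise
#' coherence images (no self-pair); \eqn{s} seed nodes yield \eqn{s(n-1)}
#' images per subject. Computing coherence between every unordered node pair
#' instead would yield \eqn{n(n-1)/2} images per subject, which is why the
#' ranking stage selects seed nodes first.
#'
#' @param n_nodes number of ROI nodes.
#' @param n_seed_nodes number of seed nodes.
#' @param n_subjects number of subjects.
#' @return Integer image count.
#' @export
scalogram_count <- function(n_nodes, n_seed_nodes = 1L, n_subjects = 1L) {
  as.integer(n_subjects) * as.integer(n_seed_nodes) * (as.integer(n_nodes) - 1L)
}

#' @rdname scalogram_count
#' @export
all_pairs_count <- function(n_nodes) {
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

#' End-to-end experiment configuration
#'
#' @param cohort a \code{\link{bold_cohort}}, a \code{\link{cohort_spec}}
#'   (generated at run time), or a manifest path.
#' @param classes class labels for the classification task; default binary
#'   \code{c("ASD","NC")}; use all four labels for the subtype task.
#' @param seed_node_mode \code{"anova_top"} (top-ranked node from the
#'   all-group ANOVA), \code{"topk"} (the \code{top_k} best-ranked nodes), or
#'   \code{"fixed"} (\code{seed_nodes} given directly). Node ranking always
#'   uses the full configured group set, even when the classification task is
#'   binary.
#' @param seed_nodes fixed node indices (mode \code{"fixed"}).
#' @param top_k number of top nodes (mode \code{"topk"}).
#' @param coherence a \code{\link{coherence_config}}; its \code{image_size}
#'   must match the CNN input.
#' @param cnn a \code{\link{cnn_config}}.
#' @param training a \code{\link{train_config}}.
#' @param protocol \code{"holdout"}, \code{"kfold"} or \code{"loso"}.
#' @param ratios hold-out ratios (protocol \code{"holdout"}).
#' @param k fold count (protocol \code{"kfold"}).
#' @param split_unit \code{"image"} (default; mirrors image-level counts) or
#'   \code{"subject"}.
#' @param out_dir output directory for run artifacts (NULL: no files written).
#' @param write_images write every scalogram as a PNG under
#'   \code{out_dir/images} (default TRUE when \code{out_dir} is set).
#' @param master_seed master integer seed driving balancing, splitting and
#'   training.
#' @return An object of class \code{experiment_config}.
#' @export
experiment_config <- function(cohort,
                              classes = c("ASD", "NC"),
                              seed_node_mode = c("anova_top", "topk", "fixed"),
                              seed_nodes = NULL, top_k = 1L,
                              coherence = coherence_config(),
                              cnn = NULL,
                              training = train_config(),
                              protocol = c("holdout", "kfold", "loso"),
                              ratios = c(0.7, 0.15, 0.15), k = 10L,
                              split_unit = c("image", "subject"),
                              out_dir = NULL, write_images = !is.null(out_dir),
                              master_seed = 1L) {
  seed_node_mode <- match.arg(seed_node_mode)
  protocol <- match.arg(protocol)
  split_unit <- match.arg(split_unit)
  if (seed_node_mode == "fixed" && is.null(seed_nodes)) {
    stop_field("seed_nodes", "required when seed_node_mode = 'fixed'")
  }
  if (!length(classes) %in% c(2L, 4L)) {
    stop_field("classes", "classification task must have 2 or 4 classes")
  }
  if (is.null(cnn)) {
    cnn <- cnn_config(input_shape = c(coherence$image_size, 3L))
  }
  if (!all(cnn$input_shape[1:2] == coherence$image_size)) {
    stop_field("cnn", "CNN input size must match coherence image_size")
  }
  structure(list(cohort = cohort, classes = classes,
                 seed_node_mode = seed_node_mode, seed_nodes = seed_nodes,
                 top_k = as.integer(top_k), coherence = coherence, cnn = cnn,
                 training = training, protocol = protocol, ratios = ratios,
                 k = as.integer(k), split_unit = split_unit,
                 out_dir = out_dir, write_images = write_images,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

resolve_cohort <- function(cfg) {
  if (inherits(cfg$cohort, "bold_cohort")) return(cfg$cohort)
  if (inherits(cfg$cohort, "cohort_spec")) return(generate_cohort(cfg$cohort))
  if (is.character(cfg$cohort)) return(load_cohort(cfg$cohort))
  stop("cohort must be a bold_cohort, cohort_spec or manifest path", call. = FALSE)
}

resolve_seed_nodes <- function(cfg, ranking) {
  switch(cfg$seed_node_mode,
    fixed = as.integer(cfg$seed_nodes),
    anova_top = {
      if (is.na(ranking$top_node)) {
        stop("no significant node: seed node undefined", call. = FALSE)
      }
      ranking$top_node
    },
    topk = {
      if (length(ranking$significant_nodes) < cfg$top_k) {
        stop(sprintf("only %d significant node(s), need %d",
                     length(ranking$significant_nodes), cfg$top_k), call. = FALSE)
      }
      ranking$significant_nodes[seq_len(cfg$top_k)]
    }
  )
}

cohort_scalograms <- function(cohort, seed_nodes, coh_cfg) {
  imgs <- list()
  for (r in cohort$recordings) {
    imgs <- c(imgs, pairwise_scalograms(r, seed_nodes, coh_cfg))
  }
  imgs
}

image_items <- function(images) {
  data.frame(
    subject_id = vapply(images, function(i) i$subject_id, character(1)),
    site = vapply(images, function(i) i$site, character(1)),
    class = vapply(images, function(i) i$group, character(1)),
    seed_node = vapply(images, function(i) i$seed_node, integer(1)),
    partner_node = vapply(images, function(i) i$partner_node, integer(1)),
    stringsAsFactors = FALSE
  )
}

fit_and_score <- function(cfg, images, items, train_idx, val_idx, test_idx) {
  model <- build_cnn(cfg$cnn, n_classes = length(cfg$classes))
  levels_y <- cfg$classes
  mk <- function(idx) {
    b <- as_image_batch(images[idx])
    b$y <- factor(as.character(b$y), levels = levels_y)
    b
  }
  tr <- mk(train_idx)
  va <- if (length(val_idx)) mk(val_idx) else NULL
  fit <- train_cnn(model, tr, va, cfg$training)
  te <- mk(test_idx)
  pred <- predict(fit, te$x)
  cm <- confusion_matrix(as.character(te$y), pred$labels, classes = levels_y)
  list(model = fit, confusion = cm, report = macro_average(cm),
       truth = as.character(te$y), predicted = pred$labels)
}

#' Run a binary or multi-class experiment end to end
#'
#' Pipeline: resolve the cohort, truncate recordings to the common length,
#' balance groups, rank nodes on the full group set, select seed node(s),
#' compute pairwise coherence scalograms for the task's classes, split, train
#' the CNN and evaluate. With an output directory set, the run writes the
#' ranking CSV, scalogram PNGs plus image manifest, metrics reports, the
#' trained model, and a provenance log of every resolved default and seed.
#'
#' @param config an \code{\link{experiment_config}}.
#' @return An object of class \code{experiment_result}: list with
#'   \code{ranking}, \code{seed_nodes}, \code{items} (image manifest),
#'   \code{report} (a \code{\link{macro_average}} report, or aggregated
#'   per-round rows for kfold/loso), \code{confusion} (pooled), \code{models},
#'   and \code{artifacts} (paths written, if any).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  cohort <- stage("load", resolve_cohort(cfg))
  cohort <- stage("truncate", truncate_to_common_length(cohort))
  cohort <- stage("balance", balance_groups(cohort, seed = cfg$master_seed))
  ranking <- stage("rank", rank_nodes(cohort))
  seed_nodes <- stage("seed-node", resolve_seed_nodes(cfg, ranking))
  task_cohort <- stage("subset", subset_groups(cohort, cfg$classes))
  images <- stage("scalograms",
                  cohort_scalograms(task_cohort, seed_nodes, cfg$coherence))
  items <- image_items(images)

  artifacts <- list()
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    artifacts$ranking <- file.path(cfg$out_dir, "ranking.csv")
    write_ranking_report(ranking, artifacts$ranking)
    if (cfg$write_images) {
      img_dir <- file.path(cfg$out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      items$file <- sprintf("%s_seed%03d_node%03d.png", items$subject_id,
                            items$seed_node, items$partner_node)
      for (i in seq_along(images)) {
        write_scalogram_png(images[[i]], file.path(img_dir, items$file[i]))
      }
      artifacts$images <- img_dir
    }
    artifacts$image_manifest <- file.path(cfg$out_dir, "image_manifest.csv")
    data.table::fwrite(items, artifacts$image_manifest)
  }

  eval_out <- stage("evaluate", {
    if (cfg$protocol == "holdout") {
      plan <- make_holdout_split(items, cfg$ratios, unit = cfg$split_unit,
                                 seed = cfg$master_seed)
      res <- fit_and_score(cfg, images, items, plan$train, plan$validation,
                           plan$test)
      list(report = res$report, confusion = res$confusion,
           models = list(res$model), plan = plan)
    } else if (cfg$protocol == "kfold") {
      plan <- kfold_plan(items, k = cfg$k, unit = cfg$split_unit,
                         seed = cfg$master_seed)
      rows <- list(); cms <- NULL; models <- list()
      for (f in seq_len(cfg$k)) {
        test_idx <- plan$folds[[f]]
        train_idx <- setdiff(seq_len(nrow(items)), test_idx)
        res <- fit_and_score(cfg, images, items, train_idx, integer(0), test_idx)
        macro <- res$report[res$report$class == "macro", -1]
        rows[[f]] <- cbind(data.frame(round = sprintf("fold%02d", f)), macro)
        cms <- if (is.null(cms)) unclass(res$confusion) else cms + unclass(res$confusion)
        models[[f]] <- res$model
      }
      list(report = aggregate_rounds(do.call(rbind, rows)),
           confusion = cms, models = models, plan = plan)
    } else {
      plan <- leave_one_site_out(items, required_classes = cfg$classes)
      rows <- list(); cms <- NULL; models <- list()
      for (s in names(plan$rounds)) {
        rd <- plan$rounds[[s]]
        res <- fit_and_score(cfg, images, items, rd$train, integer(0), rd$test)
        macro <- res$report[res$report$class == "macro", -1]
        rows[[s]] <- cbind(data.frame(round = s), macro)
        cms <- if (is.null(cms)) unclass(res$confusion) else cms + unclass(res$confusion)
        models[[s]] <- res$model
      }
      list(report = aggregate_rounds(do.call(rbind, rows)),
           confusion = cms, models = models, plan = plan)
    }
  })

  if (!is.null(cfg$out_dir)) {
    artifacts$metrics <- file.path(cfg$out_dir, "metrics.csv")
    write_metrics_report(eval_out$report, artifacts$metrics,
                         file.path(cfg$out_dir, "metrics.json"))
    artifacts$model <- file.path(cfg$out_dir, "model.rds")
    saveRDS(eval_out$models[[1]], artifacts$model)
    artifacts$provenance <- file.path(cfg$out_dir, "provenance.json")
    jsonlite::write_json(provenance_record(cfg, ranking, seed_nodes, items),
                         artifacts$provenance, auto_unbox = TRUE, digits = NA)
  }

  structure(list(ranking = ranking, seed_nodes = seed_nodes, items = items,
                 report = eval_out$report, confusion = eval_out$confusion,
                 plan = eval_out$plan, models = eval_out$models,
                 artifacts = artifacts),
            class = "experiment_result")
}

# machine-readable record of every resolved default and seed for a run
provenance_record <- function(cfg, ranking, seed_nodes, items) {
  list(
    master_seed = cfg$master_seed,
    classes = cfg$classes,
    protocol = cfg$protocol,
    split_unit = cfg$split_unit,
    ratios = cfg$ratios,
    k = cfg$k,
    seed_node_mode = cfg$seed_node_mode,
    seed_nodes = seed_nodes,
    top_node = ranking$top_node,
    alpha = ranking$alpha,
    coherence = unclass(cfg$coherence),
    cnn = unclass(cfg$cnn),
    training = unclass(cfg$training),
    n_images = nrow(items)
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d images, seed node(s): %s\n",
              nrow(x$items), paste(x$seed_nodes, collapse = ", ")))
  print(x$report)
  invisible(x)
}

#' Compare classification over combinations of the top-ranked nodes
#'
#' Builds the six node sets {1st}, {2nd}, {3rd}, {1st+2nd}, {1st+3rd},
#' {1st+2nd+3rd} from a node ranking and reports, for each, the number of
#' scalogram images per class and (unless \code{counts_only}) the test
#' accuracy of an end-to-end run using those nodes as coherence seeds.
#'
#' @param config an \code{\link{experiment_config}} (protocol
#'   \code{"holdout"} is used for the per-set runs).
#' @param counts_only if TRUE, skip training and report image counts only.
#' @return data.frame with columns \code{node_set}, \code{nodes},
#'   \code{images_per_class} and, unless \code{counts_only},
#'   \code{accuracy}.
#' @export
node_combination_study <- function(config, counts_only = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- resolve_cohort(config)
  cohort <- truncate_to_common_length(cohort)
  cohort <- balance_groups(cohort, seed = config$master_seed)
  ranking <- rank_nodes(cohort)
  if (length(ranking$significant_nodes) < 3) {
    stop(sprintf("need >= 3 significant nodes, have %d",
                 length(ranking$significant_nodes)), call. = FALSE)
  }
  top3 <- ranking$significant_nodes[1:3]
  sets <- list(`1st` = top3[1], `2nd` = top3[2], `3rd` = top3[3],
               `1st+2nd` = top3[1:2], `1st+3rd` = top3[c(1, 3)],
               `1st+2nd+3rd` = top3)
  n_nodes <- ncol(cohort$recordings[[1]]$data)
  per_class <- min(table(cohort_groups(subset_groups(cohort, config$classes))))
  rows <- lapply(names(sets), function(nm) {
    data.frame(node_set = nm,
               nodes = paste(sets[[nm]], collapse = "+"),
               images_per_class = scalogram_count(n_nodes, length(sets[[nm]]),
                                                  per_class))
  })
  out <- do.call(rbind, rows)
  if (!counts_only) {
    out$accuracy <- vapply(names(sets), function(nm) {
      cfg <- config
      cfg$seed_node_mode <- "fixed"
      cfg$seed_nodes <- sets[[nm]]
      cfg$cohort <- cohort
      cfg$out_dir <- NULL
      cfg$write_images <- FALSE
      res <- run_experiment(cfg)
      rep <- res$report
      if ("class" %in% names(rep)) {
        rep$accuracy[rep$class == "macro"]
      } else {
        rep$accuracy[rep$round == "mean"]
      }
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}
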