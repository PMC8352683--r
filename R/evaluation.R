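#' Evaluation reports
#'
#' An evaluation report stores the truth/prediction pairs of a validation
#' run together with the derived counts. The accuracy is always recomputed
#' from the counts as `(n_test - n_wrong) / n_test` (never copied from
#' elsewhere), and the identity is asserted on construction. Held-out
#' records whose class disappears from the training fold (degenerate folds)
#' are counted as wrong and flagged; none-predictions (`NA`) also count as
#' wrong.
#'
#' @param case Free-text label of the evaluated task.
#' @param level Taxonomy level or `"binary"` / `"path"`.
#' @param backend Back-end name.
#' @param truth,pred Vectors of true and predicted classes (same length;
#'   `NA` prediction = none).
#' @param degenerate Logical vector flagging degenerate folds.
#' @param seed Seed used for the run.
#' @return An object of class `triage_eval`.
#' @export
triage_eval <- function(case, level, backend, truth, pred,
                        degenerate = rep(FALSE, length(truth)), seed = NA_integer_) {
  stopifnot(length(truth) == length(pred), length(truth) == length(degenerate))
  n_test <- length(truth)
  wrong <- is.na(pred) | pred != truth
  n_wrong <- sum(wrong)
  accuracy <- (n_test - n_wrong) / n_test
  stopifnot(isTRUE(all.equal(accuracy, 1 - n_wrong / n_test)), n_wrong <= n_test)
  confusion <- dplyr::count(
    tibble::tibble(truth = as.character(truth),
                   pred = ifelse(is.na(pred), "<none>", as.character(pred))),
    .data$truth, .data$pred, name = "n")
  structure(
    list(case = case, level = level, backend = backend,
         n_test = n_test, n_wrong = n_wrong, accuracy = accuracy,
         n_degenerate = sum(degenerate), confusion = confusion,
         truth = truth, pred = pred, degenerate = degenerate, seed = seed),
    class = "triage_eval")
}

#' @export
print.triage_eval <- function(x, ...) {
  cat(sprintf("<triage_eval> %s [%s/%s]: %d/%d wrong, accuracy %.4f%s\n",
              x$case, x$level, x$backend, x$n_wrong, x$n_test, x$accuracy,
              if (x$n_degenerate > 0) sprintf(" (%d degenerate folds)", x$n_degenerate)
              else ""))
  invisible(x)
}

#' @export
tidy.triage_eval <- function(x, ...) x$confusion

#' @export
glance.triage_eval <- function(x, ...) {
  tibble::tibble(case = x$case, level = x$level, backend = x$backend,
                 n_test = x$n_test, n_wrong = x$n_wrong,
                 n_degenerate = x$n_degenerate, accuracy = x$accuracy,
                 seed = x$seed)
}

#' Confusion heatmap of an evaluation report
#'
#' @param object A `triage_eval`.
#' @param ... Unused.
#' @export
autoplot.triage_eval <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(x = .data$pred, y = .data$truth, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(title = object$case, x = "predicted", y = "true")
}

# Single-node leave-one-out loop shared by all evaluation entry points.
# Returns list(pred, degenerate).
loocv_single <- function(X, labels, backend, config, classes = NULL,
                         weights = NULL) {
  n <- nrow(X)
  pred <- rep(NA, n)
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    tr_lab <- labels[-i]
    if (!(labels[i] %in% tr_lab) || length(unique(tr_lab)) < 2) {
      degenerate[i] <- TRUE
      next
    }
    model <- fit_node(X[-i, , drop = FALSE], tr_lab, backend, config,
                      classes = sort(unique(tr_lab)))
    pred[i] <- predict_node(model, X[i, , drop = FALSE], config)
  }
  list(pred = pred, degenerate = degenerate)
}

#' Leave-one-out cross-validation of one diagnostic task
#'
#' For every record, a model is trained on all remaining records and tested
#' on the held-out one. The evaluated task is selected by `level`:
#' * `"main"` — multiclass identification of the main category over all
#'   records;
#' * `"subclass"` — identification of the subclass type given the true main
#'   category (restricted to `parent` when supplied, otherwise pooled over
#'   every populated category, each evaluated within its own records);
#' * `"disease"` — identification of the specific disease given the true
#'   subclass, analogously;
#' * `"path"` — the full cascade: a record counts as correct only when the
#'   predicted specific-disease code equals the truth.
#'
#' Folds in which the held-out class vanishes from the training data (or the
#' training data degenerate to one class) are counted as wrong and flagged.
#' The run is deterministic given `config$seed`.
#'
#' @param records Case records (symptom flags + `disease` code).
#' @param taxonomy The governing `disease_taxonomy`.
#' @param backend `"nn"`, `"svm"`, or a custom `list(fit =, predict =)`.
#' @param level `"main"`, `"subclass"`, `"disease"` or `"path"`.
#' @param parent Optional parent code restricting `"subclass"`/`"disease"`
#'   tasks to one branch.
#' @param config A [cascade_config()].
#' @return A [triage_eval()] report. For `level = "path"` the report also
#'   carries `stage_accuracy`, the per-stage correctness of the cascade
#'   (main, subclass, disease); because a stage can only be right when its
#'   parent stage routed the probe correctly, these are non-increasing.
#' @export
loocv <- function(records, taxonomy, backend = "nn",
                  level = c("main", "subclass", "disease", "path"),
                  parent = NULL, config = cascade_config()) {
  level <- match.arg(level)
  records <- validate_records(records, taxonomy)
  if (nrow(records) < 2) stop("at least two records are required", call. = FALSE)
  X <- as.matrix(records[taxonomy$symptom_names])
  anc <- code_ancestry(taxonomy, records$disease)
  backend_name <- if (is.list(backend)) "custom" else backend

  run <- function() {
    if (level == "main") {
      r <- loocv_single(X, anc$main_code, backend, config)
      return(triage_eval("main-category identification", level, backend_name,
                         anc$main_code, r$pred, r$degenerate, config$seed))
    }
    if (level == "path") {
      pred <- rep(NA_integer_, nrow(X))
      pred_main <- rep(NA_integer_, nrow(X))
      pred_sub <- rep(NA_integer_, nrow(X))
      degenerate <- logical(nrow(X))
      for (i in seq_len(nrow(X))) {
        fit <- tryCatch(
          train_cascade(records[-i, , drop = FALSE], taxonomy, backend, config),
          error = function(e) NULL)
        if (is.null(fit)) { degenerate[i] <- TRUE; next }
        d <- diagnose(fit, X[i, , drop = FALSE])
        pred[i] <- d$disease_code
        pred_main[i] <- d$main_code
        pred_sub[i] <- d$subclass_code
      }
      out <- triage_eval("full-path diagnosis", level, backend_name,
                         records$disease, pred, degenerate, config$seed)
      # per-stage correctness of the cascade: upstream errors compound, so
      # these are non-increasing down the hierarchy
      out$stage_accuracy <- c(
        main = mean(!is.na(pred_main) & pred_main == anc$main_code),
        subclass = mean(!is.na(pred_sub) & pred_sub == anc$subclass_code),
        disease = out$accuracy)
      return(out)
    }
    group_code <- if (level == "subclass") anc$main_code else anc$subclass_code
    label <- if (level == "subclass") anc$subclass_code else anc$disease
    groups <- sort(unique(group_code))
    if (!is.null(parent)) {
      if (!parent %in% groups) {
        stop(sprintf("no records under parent code %s", format(parent)),
             call. = FALSE)
      }
      groups <- parent
    }
    truth <- pred <- integer(0); degenerate <- logical(0)
    for (g in groups) {
      rows <- which(group_code == g)
      if (length(unique(label[rows])) < 2) next  # unevaluable branch
      r <- loocv_single(X[rows, , drop = FALSE], label[rows], backend, config)
      truth <- c(truth, label[rows]); pred <- c(pred, r$pred)
      degenerate <- c(degenerate, r$degenerate)
    }
    if (length(truth) == 0) {
      stop("no branch with at least two populated classes to evaluate",
           call. = FALSE)
    }
    case <- sprintf("%s identification%s", level,
                    if (!is.null(parent)) sprintf(" under %s", format(parent)) else "")
    triage_eval(case, level, backend_name, truth, pred, degenerate, config$seed)
  }
  withr::with_seed(config$seed, run())
}

#' One-vs-rest leave-one-out evaluation of a single disease
#'
#' Records about `target_code` form one class and all remaining records the
#' other; each held-out record is classified as target or other by a model
#' trained on the rest. With the SVM back-end a single hyperplane is fitted
#' (target = +1) and its membership decision is used; with the network
#' back-end a two-class model is trained.
#'
#' @param records Case records; the caller chooses the slice (for example all
#'   records of the target's subclass).
#' @param taxonomy The governing `disease_taxonomy`.
#' @param target_code Specific-disease code to identify.
#' @param backend `"nn"` or `"svm"`.
#' @param config A [cascade_config()].
#' @param weights Optional positive per-sample loss weights.
#' @return A [triage_eval()] report with level `"binary"`.
#' @export
binary_case_eval <- function(records, taxonomy, target_code,
                             backend = c("nn", "svm"),
                             config = cascade_config(), weights = NULL) {
  backend <- match.arg(backend)
  records <- validate_records(records, taxonomy)
  is_target <- records$disease == target_code
  if (!any(is_target)) {
    stop(sprintf("target code %s absent from the records", format(target_code)),
         call. = FALSE)
  }
  if (all(is_target)) {
    stop(sprintf("all records belong to target %s; the one-vs-rest task is degenerate",
                 format(target_code)), call. = FALSE)
  }
  X <- as.matrix(records[taxonomy$symptom_names])
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- rep_len(weights, n)
  labels <- ifelse(is_target, "target", "other")

  run <- function() {
    pred <- rep(NA_character_, n)
    degenerate <- logical(n)
    for (i in seq_len(n)) {
      tr_lab <- labels[-i]
      if (length(unique(tr_lab)) < 2) { degenerate[i] <- TRUE; next }
      if (backend == "svm") {
        plane <- svm_fit_binary(X[-i, , drop = FALSE],
                                ifelse(tr_lab == "target", 1, -1),
                                C = config$C, weights = weights[-i],
                                tol = config$svm_tol,
                                max_passes = config$max_passes)
        pred[i] <- ifelse(svm_decide(plane, X[i, ]) == "member", "target", "other")
      } else {
        net <- fit_symptom_nn(X[-i, , drop = FALSE], tr_lab,
                              classes = c("other", "target"),
                              eta = config$eta, epochs = config$epochs,
                              weights = weights[-i], tol = config$tol,
                              patience = config$patience)
        pred[i] <- predict(net, X[i, , drop = FALSE])
      }
    }
    triage_eval(sprintf("binary identification of %s", format(target_code)),
                "binary", backend, labels, pred, degenerate, config$seed)
  }
  withr::with_seed(config$seed, run())
}

#' Compare weighted and unweighted training on a binary task
#'
#' Runs [binary_case_eval()] twice under the same seed — once with uniform
#' weights, once with the supplied clinical weights — and reports the
#' absolute difference in accuracy.
#'
#' @inheritParams binary_case_eval
#' @param weights Positive per-record loss weights for the weighted run.
#' @return A list with `unweighted`, `weighted` (both [triage_eval()]
#'   reports) and `delta` (absolute accuracy difference, fraction in [0,1]).
#' @export
weighted_comparison <- function(records, taxonomy, target_code, weights,
                                backend = c("nn", "svm"),
                                config = cascade_config()) {
  backend <- match.arg(backend)
  unweighted <- binary_case_eval(records, taxonomy, target_code, backend, config,
                                 weights = NULL)
  weighted <- binary_case_eval(records, taxonomy, target_code, backend, config,
                               weights = weights)
  list(unweighted = unweighted, weighted = weighted,
       delta = abs(weighted$accuracy - unweighted$accuracy))
}

#' Combine evaluation reports into a results table
#'
#' @param reports A list of [triage_eval()] objects.
#' @return A tibble with columns `case`, `level`, `backend`, `n_test`,
#'   `n_wrong`, `accuracy` (one row per report; header-only when empty).
#' @export
report_table <- function(reports) {
  if (length(reports) == 0) {
    return(tibble::tibble(case = character(), level = character(),
                          backend = character(), n_test = integer(),
                          n_wrong = integer(), accuracy = double()))
  }
  dplyr::select(purrr::map_dfr(reports, glance),
                "case", "level", "backend", "n_test", "n_wrong", "accuracy")
}

#' Render or persist a results table
#'
#' `format_report_table()` returns an aligned text rendering;
#' `write_report_table()` writes CSV that reparses to identical numbers.
#'
#' @param table A tibble from [report_table()].
#' @param path Output CSV path.
#' @export
format_report_table <- function(table) {
  df <- as.data.frame(table)
  df$accuracy <- formatC(df$accuracy, format = "f", digits = 4)
  paste(utils::capture.output(print(df, row.names = FALSE)), collapse = "\n")
}

#' @rdname format_report_table
#' @export
write_report_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}
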