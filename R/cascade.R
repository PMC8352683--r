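#' Configuration for cascade training and evaluation
#'
#' Collects the tunable parameters of both back-ends and of the diagnostic
#' procedure. `svm_mode` selects how the one-vs-rest hyperplane sets emit a
#' class: `"argmax"` (largest decision value, always returns a class) or
#' `"sequential"` (first firing plane in class order; may return none).
#' `conditioning` selects whether lower levels are conditioned on the
#' predicted parent (pure cascade) or on a supplied true parent.
#'
#' @param eta Learning rate of the network back-end.
#' @param epochs Maximum training epochs of the network back-end.
#' @param C Soft-margin penalty of the SVM back-end.
#' @param seed Integer seed governing all randomness of a training run.
#' @param svm_mode `"argmax"` or `"sequential"`.
#' @param conditioning `"predicted"` or `"given"`.
#' @param tol,patience Early-stopping rule of the network back-end.
#' @param svm_tol,max_passes Convergence control of the SVM solver.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(eta = 0.1, epochs = 200, C = 1, seed = 1L,
                           svm_mode = c("argmax", "sequential"),
                           conditioning = c("predicted", "given"),
                           tol = 1e-6, patience = 10,
                           svm_tol = 0.1, max_passes = 1e5) {
  structure(
    list(eta = eta, epochs = epochs, C = C, seed = as.integer(seed),
         svm_mode = match.arg(svm_mode), conditioning = match.arg(conditioning),
         tol = tol, patience = patience, svm_tol = svm_tol,
         max_passes = max_passes),
    class = "cascade_config")
}

#' Read a cascade configuration from a YAML file
#'
#' Recognised keys are the arguments of [cascade_config()]; missing keys take
#' the defaults.
#'
#' @param path YAML file path.
#' @return A `cascade_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cascade_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(cascade_config, vals)
}

# ---- single-node fit/predict dispatch -------------------------------------
# A "node" is one classifier over the children of one taxonomy position.
# backend: "nn", "svm", or a list(fit = function(X, codes, classes, config),
# predict = function(model, X)) for custom/back-end-agnostic testing.
fit_node <- function(X, codes, backend, config, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(codes))
  if (is.list(backend)) {
    return(structure(list(model = backend$fit(X, codes, classes, config),
                          predict_fn = backend$predict, classes = classes),
                     class = "custom_node"))
  }
  switch(backend,
    nn = fit_symptom_nn(X, codes, classes = classes, eta = config$eta,
                        epochs = config$epochs, tol = config$tol,
                        patience = config$patience),
    svm = fit_one_vs_rest(X, codes, classes = classes, C = config$C,
                          tol = config$svm_tol, max_passes = config$max_passes),
    stop(sprintf("unknown backend '%s'", backend), call. = FALSE))
}

predict_node <- function(model, X, config) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (inherits(model, "passthrough_node")) return(rep(model$code, nrow(X)))
  if (inherits(model, "custom_node")) return(model$predict_fn(model$model, X))
  if (inherits(model, "symptom_nn")) return(predict(model, X))
  predict(model, X, mode = config$svm_mode)
}

# Raw per-class scores of a node (softmax probabilities or decision values);
# NULL for pass-through nodes.
node_scores <- function(model, X, config) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (inherits(model, "passthrough_node") || inherits(model, "custom_node")) return(NULL)
  if (inherits(model, "symptom_nn")) return(predict(model, X, type = "prob"))
  predict(model, X, type = "score")
}

#' Train the three-level diagnostic cascade
#'
#' Expands the records into per-level training sets and trains one model per
#' populated taxonomy node: a main-category model on all records, one
#' subclass model per populated category, and one specific-disease model per
#' populated subclass. A node whose training data contain a single populated
#' child is represented as a pass-through (its prediction is that only
#' child) and noted in the model; the main level must have at least two
#' populated categories. Training is deterministic given `config$seed`.
#'
#' @param records Case records (symptom flags + `disease` leaf code).
#' @param taxonomy The governing `disease_taxonomy`.
#' @param backend `"nn"` or `"svm"`.
#' @param config A [cascade_config()].
#' @return An object of class `triage_cascade`.
#' @export
train_cascade <- function(records, taxonomy, backend = c("nn", "svm"),
                          config = cascade_config()) {
  if (!is.list(backend) || is.null(backend$fit)) backend <- match.arg(backend)
  records <- validate_records(records, taxonomy)
  X <- as.matrix(records[taxonomy$symptom_names])
  anc <- code_ancestry(taxonomy, records$disease)
  notes <- character(0)

  build <- function() {
    main_classes <- sort(unique(anc$main_code))
    if (length(main_classes) < 2) {
      stop("main level has fewer than two populated categories", call. = FALSE)
    }
    main_model <- fit_node(X, anc$main_code, backend, config, main_classes)

    subclass_models <- list()
    for (mc in main_classes) {
      rows <- which(anc$main_code == mc)
      kids <- sort(unique(anc$subclass_code[rows]))
      if (length(kids) < 2) {
        notes <<- c(notes, sprintf(
          "category %d has a single populated subclass %d; pass-through", mc, kids))
        subclass_models[[as.character(mc)]] <-
          structure(list(code = kids), class = "passthrough_node")
      } else {
        subclass_models[[as.character(mc)]] <-
          fit_node(X[rows, , drop = FALSE], anc$subclass_code[rows], backend,
                   config, kids)
      }
    }

    disease_models <- list()
    for (sc in sort(unique(anc$subclass_code))) {
      rows <- which(anc$subclass_code == sc)
      kids <- sort(unique(anc$disease[rows]))
      if (length(kids) < 2) {
        notes <<- c(notes, sprintf(
          "subclass %d has a single populated disease %d; pass-through", sc, kids))
        disease_models[[as.character(sc)]] <-
          structure(list(code = kids), class = "passthrough_node")
      } else {
        disease_models[[as.character(sc)]] <-
          fit_node(X[rows, , drop = FALSE], anc$disease[rows], backend,
                   config, kids)
      }
    }
    list(main = main_model, subclass = subclass_models, disease = disease_models)
  }

  models <- withr::with_seed(config$seed, build())
  structure(
    list(backend = if (is.list(backend)) "custom" else backend,
         main_model = models$main, subclass_models = models$subclass,
         disease_models = models$disease, taxonomy = taxonomy,
         config = config, notes = notes),
    class = "triage_cascade")
}

#' @export
print.triage_cascade <- function(x, ...) {
  cat(sprintf("<triage_cascade> backend=%s: 1 main + %d subclass + %d disease node(s)\n",
              x$backend, length(x$subclass_models), length(x$disease_models)))
  if (length(x$notes)) cat(" notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Diagnose symptom vectors with a trained cascade
#'
#' Runs the three identification stages: the main model proposes a category,
#' which selects the subclass model to run, whose prediction selects the
#' specific-disease model. When a stage emits no class (sequential SVM mode
#' with no firing plane) or no model exists for the selected parent, that
#' level and everything below it are absent (`NA`). With
#' `conditioning = "given"` in the model's config, `newdata` must carry a
#' `disease` column whose true ancestors condition the lower stages instead
#' of the predictions.
#'
#' @param model A `triage_cascade`.
#' @param newdata A data frame of symptom flags (taxonomy symptom columns),
#'   a numeric vector, or a matrix.
#' @return A tibble with one row per probe: `main_code`, `subclass_code`,
#'   `disease_code`, and list-columns `main_scores`, `subclass_scores`,
#'   `disease_scores` holding named per-class raw scores (NULL where the
#'   stage did not run a scored model).
#' @export
diagnose <- function(model, newdata) {
  stopifnot(inherits(model, "triage_cascade"))
  tax <- model$taxonomy
  config <- model$config
  given <- NULL
  if (is.data.frame(newdata)) {
    nd <- tibble::as_tibble(newdata)
    if ("disease" %in% names(nd)) {
      given <- code_ancestry(tax, nd$disease)
      nd <- dplyr::select(nd, -"disease")
    }
    X <- as.matrix(nd[tax$symptom_names])
  } else {
    if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
    X <- as.matrix(newdata)
  }
  if (ncol(X) != length(tax$symptom_names)) {
    stop(sprintf("probes have %d symptom columns; taxonomy declares %d",
                 ncol(X), length(tax$symptom_names)), call. = FALSE)
  }
  n <- nrow(X)
  use_given <- config$conditioning == "given"
  if (use_given && is.null(given)) {
    stop("conditioning = 'given' requires a `disease` column in `newdata`",
         call. = FALSE)
  }

  main_pred <- predict_node(model$main_model, X, config)
  main_sc <- node_scores(model$main_model, X, config)
  sub_pred <- rep(NA_integer_, n)
  dis_pred <- rep(NA_integer_, n)
  sub_sc <- vector("list", n)
  dis_sc <- vector("list", n)

  cond_main <- if (use_given) given$main_code else main_pred
  for (mc in unique(cond_main[!is.na(cond_main)])) {
    rows <- which(!is.na(cond_main) & cond_main == mc)
    sm <- model$subclass_models[[as.character(mc)]]
    if (is.null(sm)) next
    sub_pred[rows] <- predict_node(sm, X[rows, , drop = FALSE], config)
    sc <- node_scores(sm, X[rows, , drop = FALSE], config)
    if (!is.null(sc)) for (k in seq_along(rows)) sub_sc[[rows[k]]] <- sc[k, ]
  }
  cond_sub <- if (use_given) given$subclass_code else sub_pred
  for (sc_code in unique(cond_sub[!is.na(cond_sub)])) {
    rows <- which(!is.na(cond_sub) & cond_sub == sc_code)
    dm <- model$disease_models[[as.character(sc_code)]]
    if (is.null(dm)) next
    dis_pred[rows] <- predict_node(dm, X[rows, , drop = FALSE], config)
    sc <- node_scores(dm, X[rows, , drop = FALSE], config)
    if (!is.null(sc)) for (k in seq_along(rows)) dis_sc[[rows[k]]] <- sc[k, ]
  }
  main_sc_list <- if (is.null(main_sc)) vector("list", n) else
    lapply(seq_len(n), function(i) main_sc[i, ])
  tibble::tibble(
    main_code = main_pred, subclass_code = sub_pred, disease_code = dis_pred,
    main_scores = main_sc_list, subclass_scores = sub_sc, disease_scores = dis_sc)
}

#' @export
glance.triage_cascade <- function(x, ...) {
  tibble::tibble(backend = x$backend,
                 n_subclass_nodes = length(x$subclass_models),
                 n_disease_nodes = length(x$disease_models),
                 n_passthrough = sum(vapply(c(x$subclass_models, x$disease_models),
                                            inherits, logical(1), "passthrough_node")),
                 seed = x$config$seed)
}

#' @export
tidy.triage_cascade <- function(x, ...) {
  node_row <- function(model, level, parent) {
    tibble::tibble(level = level, parent_code = parent,
                   kind = class(model)[1],
                   n_classes = if (inherits(model, "passthrough_node")) 1L
                               else length(model$classes))
  }
  rows <- list(node_row(x$main_model, "main", NA_integer_))
  for (nm in names(x$subclass_models)) {
    rows[[length(rows) + 1L]] <- node_row(x$subclass_models[[nm]], "subclass",
                                          as.integer(nm))
  }
  for (nm in names(x$disease_models)) {
    rows[[length(rows) + 1L]] <- node_row(x$disease_models[[nm]], "disease",
                                          as.integer(nm))
  }
  dplyr::bind_rows(rows)
}

# ---- concurrence (composite-class) diagnosis ------------------------------

#' Train a classifier over declared disease concurrences
#'
#' A concurrence case is a single symptom vector arising from two or three
#' co-occurring diseases of different types; each declared combination is
#' treated as one composite class and a standard single-label model is
#' trained over the combinations.
#'
#' @param records A data frame with the taxonomy's symptom columns plus a
#'   `combo` column naming each record's combination.
#' @param taxonomy The governing `disease_taxonomy`.
#' @param combos A named list of integer code vectors; each must hold 2 or 3
#'   distinct codes at a common taxonomy level.
#' @param backend `"nn"` or `"svm"`.
#' @param config A [cascade_config()].
#' @return An object of class `concurrence_model`.
#' @export
train_concurrence <- function(records, taxonomy, combos,
                              backend = c("nn", "svm"),
                              config = cascade_config()) {
  backend <- match.arg(backend)
  validate_combos(taxonomy, combos)
  if (length(combos) < 2) stop("at least two combinations are required", call. = FALSE)
  records <- tibble::as_tibble(records)
  if (!all(c(taxonomy$symptom_names, "combo") %in% names(records))) {
    stop("records must carry the taxonomy symptom columns and a `combo` column",
         call. = FALSE)
  }
  unknown <- setdiff(unique(records$combo), names(combos))
  if (length(unknown) > 0) {
    stop(sprintf("record combination(s) not declared: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  X <- as.matrix(records[taxonomy$symptom_names])
  model <- withr::with_seed(config$seed,
    fit_node(X, records$combo, backend, config, classes = sort(names(combos))))
  structure(list(backend = backend, model = model, combos = combos,
                 taxonomy = taxonomy, config = config),
            class = "concurrence_model")
}

validate_combos <- function(taxonomy, combos) {
  if (is.null(names(combos)) || any(names(combos) == "")) {
    stop("`combos` must be a named list", call. = FALSE)
  }
  for (nm in names(combos)) {
    codes <- combos[[nm]]
    if (!length(codes) %in% c(2L, 3L) || anyDuplicated(codes)) {
      stop(sprintf("combination '%s' must hold 2 or 3 distinct codes", nm),
           call. = FALSE)
    }
    lv <- vapply(codes, function(cd) decode_code(taxonomy, cd)$level, character(1))
    if (length(unique(lv)) != 1) {
      stop(sprintf("combination '%s' mixes taxonomy levels", nm), call. = FALSE)
    }
  }
  invisible(combos)
}

#' Diagnose concurrence cases
#'
#' @param model A `concurrence_model`.
#' @param newdata Symptom data frame / matrix / vector.
#' @return A tibble with `combo` (predicted combination name), the member
#'   codes as a list-column, and per-class raw scores.
#' @export
diagnose_concurrence <- function(model, newdata) {
  stopifnot(inherits(model, "concurrence_model"))
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(tibble::as_tibble(newdata)[model$taxonomy$symptom_names])
  } else if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  pred <- predict_node(model$model, newdata, model$config)
  sc <- node_scores(model$model, newdata, model$config)
  tibble::tibble(
    combo = pred,
    member_codes = lapply(pred, function(p) if (is.na(p)) NULL else model$combos[[p]]),
    scores = if (is.null(sc)) vector("list", length(pred))
             else lapply(seq_along(pred), function(i) sc[i, ]))
}
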