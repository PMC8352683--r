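#' Persist and restore fitted models as JSON
#'
#' Models are stored as plain JSON at full double precision: networks with
#' their dimensions, learning rate, class labels and both weight matrices
#' (row-major); one-vs-rest hyperplane sets with their level annotation and
#' per-class `(omega, c)` pairs; cascades as the nested collection of their
#' node models plus the taxonomy.
#'
#' @param model A `symptom_nn`, `linear_svm`, `ovr_svm` or `triage_cascade`.
#' @param path Output file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   restored model.
#' @export
write_model <- function(model, path) {
  # I(17) significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(serialize_model(model), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  deserialize_model(jsonlite::read_json(path, simplifyVector = FALSE))
}

serialize_model <- function(model) {
  if (inherits(model, "symptom_nn")) {
    return(list(type = "symptom_nn", n_in = model$n_in, n_hidden = model$n_hidden,
                n_out = model$n_out, eta = model$eta, seed = model$seed,
                classes = model$classes, epochs_run = model$epochs_run,
                W_in = as.vector(t(model$W_in)), W_out = as.vector(t(model$W_out))))
  }
  if (inherits(model, "linear_svm")) {
    return(list(type = "linear_svm", omega = model$omega, c = model$c))
  }
  if (inherits(model, "ovr_svm")) {
    return(list(type = "ovr_svm", level = model$level,
                parent_code = model$parent_code, classes = model$classes,
                planes = lapply(seq_along(model$classes), function(i) {
                  list(code = model$classes[i],
                       omega = model$planes[[i]]$omega, c = model$planes[[i]]$c)
                })))
  }
  if (inherits(model, "passthrough_node")) {
    return(list(type = "passthrough", code = model$code))
  }
  if (inherits(model, "triage_cascade")) {
    return(list(
      type = "triage_cascade", backend = model$backend,
      notes = as.list(model$notes), config = unclass(model$config),
      taxonomy = taxonomy_as_list(model$taxonomy),
      main_model = serialize_model(model$main_model),
      subclass_models = lapply(model$subclass_models, serialize_model),
      disease_models = lapply(model$disease_models, serialize_model)))
  }
  stop("unsupported model class", call. = FALSE)
}

# `doc` is unsimplified parsed JSON (lists all the way down).
deserialize_model <- function(doc) {
  num <- function(x) vapply(x, as.numeric, numeric(1))
  switch(doc$type,
    symptom_nn = structure(
      list(n_in = doc$n_in, n_hidden = doc$n_hidden, n_out = doc$n_out,
           eta = doc$eta, classes = unlist(doc$classes),
           W_in = matrix(num(doc$W_in), doc$n_in + 1L, doc$n_hidden, byrow = TRUE),
           W_out = matrix(num(doc$W_out), doc$n_hidden + 1L, doc$n_out,
                          byrow = TRUE),
           seed = doc$seed, loss_history = numeric(0),
           epochs_run = doc$epochs_run %||% 0L),
      class = "symptom_nn"),
    linear_svm = structure(
      list(omega = num(doc$omega), c = doc$c, alpha = NULL,
           passes = NA_integer_, converged = TRUE),
      class = "linear_svm"),
    ovr_svm = {
      planes <- lapply(doc$planes, function(p) {
        structure(list(omega = num(p$omega), c = p$c, alpha = NULL,
                       passes = NA_integer_, converged = TRUE),
                  class = "linear_svm")
      })
      classes <- unlist(doc$classes)
      names(planes) <- as.character(classes)
      structure(list(level = doc$level %||% NA_character_,
                     parent_code = doc$parent_code %||% NA_integer_,
                     classes = classes, planes = planes),
                class = "ovr_svm")
    },
    passthrough = structure(list(code = doc$code), class = "passthrough_node"),
    triage_cascade = {
      cfg <- doc$config
      config <- cascade_config(
        eta = cfg$eta, epochs = cfg$epochs, C = cfg$C, seed = cfg$seed,
        svm_mode = cfg$svm_mode, conditioning = cfg$conditioning,
        tol = cfg$tol, patience = cfg$patience, svm_tol = cfg$svm_tol,
        max_passes = cfg$max_passes)
      structure(
        list(backend = doc$backend,
             main_model = deserialize_model(doc$main_model),
             subclass_models = lapply(doc$subclass_models, deserialize_model),
             disease_models = lapply(doc$disease_models, deserialize_model),
             taxonomy = taxonomy_from_list(doc$taxonomy), config = config,
             notes = unlist(doc$notes) %||% character(0)),
        class = "triage_cascade")
    },
    stop("unrecognised model file", call. = FALSE))
}
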