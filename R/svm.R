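#' Fit a soft-margin linear SVM to a binary task
#'
#' Solves the weighted soft-margin problem
#' `min 1/2 (||omega||^2 + c^2) + C sum_k w_k xi_k` subject to
#' `y_k (omega . x_k + c) >= 1 - xi_k`, `xi_k >= 0`, by coordinate descent on
#' the dual with box constraints `0 <= alpha_k <= C w_k`. The intercept is
#' carried as an augmented constant feature, which makes the primal strictly
#' convex: the fitted hyperplane is unique and independent of sample order.
#' Hard-margin behaviour is approximated by a large `C` (e.g. `1e4`): on
#' separable data all margins then satisfy `y f(x) >= 1` up to the solver
#' tolerance. Per-sample weights are normalised to mean 1, so uniform weight
#' vectors reproduce the unweighted fit exactly.
#'
#' @param X Numeric matrix/data frame of samples, `n x N`.
#' @param y Labels in `{+1, -1}` (class of interest = +1).
#' @param C Positive soft-margin penalty.
#' @param weights Optional positive per-sample weights.
#' @param tol Convergence tolerance on the maximal projected dual gradient.
#' @param max_passes Maximum number of full passes over the data.
#' @return An object of class `linear_svm` with elements `omega` (length-N
#'   weight vector), `c` (intercept), `alpha`, `passes`, `converged`.
#' @export
svm_fit_binary <- function(X, y, C = 1, weights = NULL, tol = 1e-8,
                           max_passes = 1e5) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!all(y %in% c(-1, 1))) stop("`y` must contain only +1/-1 labels", call. = FALSE)
  if (length(y) != n) stop("`y` must match the number of rows of X", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both classes must be present to fit a separating hyperplane", call. = FALSE)
  }
  if (!is.numeric(C) || C <= 0) stop("`C` must be > 0", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- rep_len(weights, n)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  weights <- weights / mean(weights)
  res <- svm_dcd_cpp(X, as.numeric(y), C * weights, tol, as.integer(max_passes))
  if (!res$converged) {
    stop(sprintf("SVM solver did not converge after %d passes (max violation %.3g)",
                 res$passes, res$violation), call. = FALSE)
  }
  structure(
    list(omega = drop(res$w), c = res$c, alpha = drop(res$alpha),
         passes = res$passes, converged = res$converged),
    class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> %d features, |omega|=%.4g, c=%.4g (%d passes)\n",
              length(x$omega), sqrt(sum(x$omega^2)), x$c, x$passes))
  invisible(x)
}

#' Raw decision value of a hyperplane
#'
#' `omega . x + c`, the quantity whose sign drives [svm_decide()].
#'
#' @param plane A `linear_svm`.
#' @param X A symptom vector or a matrix of row vectors.
#' @return A numeric decision value per input row.
#' @export
svm_score <- function(plane, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != length(plane$omega)) {
    stop(sprintf("input has %d features; hyperplane expects %d",
                 ncol(X), length(plane$omega)), call. = FALSE)
  }
  drop(X %*% plane$omega + plane$c)
}

#' Membership decision of a fitted hyperplane
#'
#' A symptom vector is a member of the hyperplane's class iff
#' `omega . x + c > 0` and a non-member iff `< 0`. A decision value of
#' exactly 0 is on the boundary and is resolved as non-member (documented
#' tie rule).
#'
#' @param plane A `linear_svm`.
#' @param x Symptom vector (or matrix of vectors).
#' @return `"member"` / `"nonmember"` per input row.
#' @export
svm_decide <- function(plane, x) {
  ifelse(svm_score(plane, x) > 0, "member", "nonmember")
}

#' Fit a one-vs-rest set of hyperplanes at one taxonomy level
#'
#' For each class at the level, fits [svm_fit_binary()] with that class
#' mapped to +1 and all others to -1. Plane order follows `classes`
#' (taxonomy order by default: ascending code).
#'
#' @param X Samples, `n x N`.
#' @param codes Class code per sample.
#' @param classes Optional full ordered class set; every class must have at
#'   least one sample. Defaults to `sort(unique(codes))`.
#' @param C,weights,tol,max_passes Passed to [svm_fit_binary()].
#' @param level,parent_code Optional annotations (taxonomy level of the
#'   classes and their common parent code).
#' @return An object of class `ovr_svm` with one `linear_svm` per class.
#' @export
fit_one_vs_rest <- function(X, codes, classes = NULL, C = 1, weights = NULL,
                            tol = 1e-8, max_passes = 1e5,
                            level = NA_character_, parent_code = NA_integer_) {
  if (is.null(classes)) classes <- sort(unique(codes))
  if (length(classes) < 2) stop("at least two classes are required", call. = FALSE)
  missing <- setdiff(classes, codes)
  if (length(missing) > 0) {
    stop(sprintf("no samples for class %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  planes <- lapply(classes, function(cl) {
    svm_fit_binary(X, ifelse(codes == cl, 1, -1), C = C, weights = weights,
                   tol = tol, max_passes = max_passes)
  })
  names(planes) <- as.character(classes)
  structure(list(level = level, parent_code = parent_code,
                 classes = classes, planes = planes),
            class = "ovr_svm")
}

#' @export
print.ovr_svm <- function(x, ...) {
  cat(sprintf("<ovr_svm> %d classes at level %s (parent %s)\n",
              length(x$classes), x$level, format(x$parent_code)))
  invisible(x)
}

# All decision values for one input row (named by class code).
ovr_scores <- function(set, x) {
  vapply(set$planes, function(p) svm_score(p, x), numeric(1))
}

#' Sequential one-vs-rest identification
#'
#' Scans the hyperplanes in class order and returns the first class whose
#' decision is "member"; when no plane fires the procedure quits and `NA` is
#' returned (no class identified).
#'
#' @param set An `ovr_svm`.
#' @param x Symptom vector.
#' @return A class code, or `NA` when no plane fires.
#' @export
sequential_identify <- function(set, x) {
  for (i in seq_along(set$classes)) {
    if (svm_score(set$planes[[i]], x) > 0) return(set$classes[i])
  }
  set$classes[NA_integer_]
}

#' Maximum-score one-vs-rest identification
#'
#' Returns the class whose hyperplane has the largest decision value
#' `omega . x + c`; ties are broken toward the lowest class code. Unlike
#' [sequential_identify()], this always returns a class, which makes it the
#' default identification mode of the cascade (the sequential loop can
#' return none, and is order dependent when several planes fire).
#'
#' @inheritParams sequential_identify
#' @return A class code.
#' @export
argmax_identify <- function(set, x) {
  set$classes[which.max(ovr_scores(set, x))]
}

#' Predict class codes from a one-vs-rest hyperplane set
#'
#' @param object An `ovr_svm`.
#' @param newdata Symptom matrix/data frame (or single vector).
#' @param mode `"argmax"` (default) or `"sequential"`.
#' @param type `"class"` or `"score"` (matrix of decision values).
#' @param ... Unused.
#' @export
predict.ovr_svm <- function(object, newdata, mode = c("argmax", "sequential"),
                            type = c("class", "score"), ...) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  S <- vapply(object$planes, function(p) svm_score(p, newdata),
              numeric(nrow(newdata)))
  S <- matrix(S, nrow = nrow(newdata),
              dimnames = list(NULL, as.character(object$classes)))
  if (type == "score") return(S)
  if (mode == "argmax") {
    object$classes[max.col(S, ties.method = "first")]
  } else {
    first <- apply(S, 1, function(s) {
      i <- which(s > 0)
      if (length(i) == 0) NA_integer_ else i[1]
    })
    object$classes[first]
  }
}

#' @export
tidy.linear_svm <- function(x, ...) {
  tibble::tibble(term = c(paste0("omega_", seq_along(x$omega)), "c"),
                 estimate = c(x$omega, x$c))
}

#' @export
glance.linear_svm <- function(x, ...) {
  tibble::tibble(n_features = length(x$omega), norm_omega = sqrt(sum(x$omega^2)),
                 intercept = x$c, n_sv = sum(x$alpha > 1e-8), passes = x$passes,
                 converged = x$converged)
}

#' @export
tidy.ovr_svm <- function(x, ...) {
  purrr::map2_dfr(x$planes, x$classes, function(p, cl) {
    dplyr::mutate(tidy(p), class = cl, .before = 1)
  })
}

#' @export
glance.ovr_svm <- function(x, ...) {
  tibble::tibble(level = x$level, parent_code = x$parent_code,
                 n_classes = length(x$classes))
}
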