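#' Build a three-level disease taxonomy
#'
#' Diseases are organised as main categories, subclass disease types and
#' specific diseases, with integer codes generated arithmetically from a
#' `code_base`: category `b` gets `code_base * 10 + b`, subclass `j` under it
#' gets `(category code) * 10 + j`, and disease `t` under that gets
#' `(subclass code) * 10 + t`. Because the `j` and `t` suffixes occupy a
#' single decimal digit, each category may hold at most 9 subclasses and each
#' subclass at most 9 diseases; the number of categories is not limited by the
#' scheme itself (codes are checked for global uniqueness).
#'
#' Symptom 1 is by convention the patient's gender (flag 1 = male, 0 =
#' female), treated as a pseudo-symptom so that the same somatic symptoms can
#' map to different diseases by gender.
#'
#' @param categories A list, one element per main category, each a list with
#'   `name` and optionally `subclasses`; each subclass is a list with `name`
#'   and optionally `diseases` (a list of lists with `name`, or a character
#'   vector of names).
#' @param symptom_names Character vector of symptom names; element 1 is the
#'   gender pseudo-symptom.
#' @param code_base Positive integer used as the base of the code arithmetic.
#' @return An object of class `disease_taxonomy`.
#' @examples
#' tax <- disease_taxonomy(
#'   categories = list(
#'     list(name = "digestive", subclasses = list(
#'       list(name = "stomach", diseases = c("gastritis", "gastric_ulcer")))),
#'     list(name = "respiratory")
#'   ),
#'   symptom_names = c("gender", "fever", "cough", "pain")
#' )
#' encode_code(tax, b = 1, j = 1, t = 2)
#' @export
disease_taxonomy <- function(categories, symptom_names, code_base = 10) {
  stopifnot(is.numeric(code_base), length(code_base) == 1, code_base >= 1,
            code_base == as.integer(code_base))
  code_base <- as.integer(code_base)
  if (!is.character(symptom_names) || length(symptom_names) < 1) {
    stop("`symptom_names` must be a non-empty character vector", call. = FALSE)
  }
  if (anyDuplicated(symptom_names)) {
    stop("symptom names must be unique", call. = FALSE)
  }
  if (length(categories) < 1) stop("at least one category is required", call. = FALSE)

  rows <- list()
  for (b in seq_along(categories)) {
    cat_spec <- categories[[b]]
    if (is.character(cat_spec)) cat_spec <- list(name = cat_spec)
    cat_code <- code_base * 10L + b
    rows[[length(rows) + 1L]] <- tibble::tibble(
      code = cat_code, level = "main", name = cat_spec$name %||% paste0("category_", b),
      b = b, j = NA_integer_, t = NA_integer_, parent_code = NA_integer_)
    subs <- cat_spec$subclasses %||% list()
    if (length(subs) > 9) {
      stop(sprintf("category %d declares %d subclasses; the code scheme allows at most 9",
                   b, length(subs)), call. = FALSE)
    }
    for (j in seq_along(subs)) {
      sub_spec <- subs[[j]]
      if (is.character(sub_spec)) sub_spec <- list(name = sub_spec)
      sub_code <- cat_code * 10L + j
      rows[[length(rows) + 1L]] <- tibble::tibble(
        code = sub_code, level = "subclass",
        name = sub_spec$name %||% paste0("subclass_", b, "_", j),
        b = b, j = j, t = NA_integer_, parent_code = cat_code)
      dis <- sub_spec$diseases %||% list()
      if (is.character(dis)) dis <- lapply(dis, function(nm) list(name = nm))
      if (length(dis) > 9) {
        stop(sprintf("subclass (%d,%d) declares %d diseases; the code scheme allows at most 9",
                     b, j, length(dis)), call. = FALSE)
      }
      for (t in seq_along(dis)) {
        d_spec <- dis[[t]]
        if (is.character(d_spec)) d_spec <- list(name = d_spec)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          code = sub_code * 10L + t, level = "disease",
          name = d_spec$name %||% paste0("disease_", b, "_", j, "_", t),
          b = b, j = j, t = t, parent_code = sub_code)
      }
    }
  }
  nodes <- dplyr::bind_rows(rows)
  if (anyDuplicated(nodes$code)) {
    dup <- nodes$code[duplicated(nodes$code)][1]
    stop(sprintf("code arithmetic produced duplicate code %d; choose a larger code_base",
                 dup), call. = FALSE)
  }
  structure(
    list(code_base = code_base, symptom_names = symptom_names, nodes = nodes),
    class = "disease_taxonomy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.disease_taxonomy <- function(x, ...) {
  n <- table(factor(x$nodes$level, levels = c("main", "subclass", "disease")))
  cat(sprintf(
    "<disease_taxonomy> code_base=%d, %d symptoms, %d categories / %d subclasses / %d diseases\n",
    x$code_base, length(x$symptom_names), n[["main"]], n[["subclass"]], n[["disease"]]))
  invisible(x)
}

#' Tabulate all codes of a taxonomy
#'
#' @param taxonomy A `disease_taxonomy`.
#' @return A tibble with one row per registered code: `code`, `level`, `name`,
#'   the level indices `b`, `j`, `t` and `parent_code`.
#' @export
taxonomy_codes <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "disease_taxonomy"))
  taxonomy$nodes
}

#' Encode a taxonomy path as an integer disease code
#'
#' Applies the code arithmetic of the hierarchy: depth-1 paths give category
#' codes `code_base*10 + b`, depth-2 give subclass codes, depth-3 give
#' specific-disease codes.
#'
#' @inheritParams taxonomy_codes
#' @param b Main-category index.
#' @param j Optional subclass index within category `b`.
#' @param t Optional disease index within subclass `(b, j)`.
#' @return The integer code.
#' @export
encode_code <- function(taxonomy, b, j = NULL, t = NULL) {
  stopifnot(inherits(taxonomy, "disease_taxonomy"))
  nodes <- taxonomy$nodes
  n_cat <- sum(nodes$level == "main")
  if (!is.numeric(b) || length(b) != 1 || b < 1 || b > n_cat) {
    stop(sprintf("main-category index b=%s out of range 1..%d", format(b), n_cat),
         call. = FALSE)
  }
  code <- taxonomy$code_base * 10L + as.integer(b)
  if (is.null(j)) {
    if (!is.null(t)) stop("`t` given without `j`", call. = FALSE)
    return(code)
  }
  n_sub <- sum(nodes$level == "subclass" & nodes$b == b)
  if (!is.numeric(j) || length(j) != 1 || j < 1 || j > n_sub) {
    stop(sprintf("subclass index j=%s out of range 1..%d for category %d",
                 format(j), n_sub, b), call. = FALSE)
  }
  code <- code * 10L + as.integer(j)
  if (is.null(t)) return(code)
  n_dis <- sum(nodes$level == "disease" & nodes$b == b & nodes$j == j)
  if (!is.numeric(t) || length(t) != 1 || t < 1 || t > n_dis) {
    stop(sprintf("disease index t=%s out of range 1..%d for subclass (%d,%d)",
                 format(t), n_dis, b, j), call. = FALSE)
  }
  code * 10L + as.integer(t)
}

#' Decode an integer disease code
#'
#' The inverse of [encode_code()]. Level identification is by taxonomy lookup,
#' not digit counting, so codes remain unambiguous for any `code_base`.
#'
#' @inheritParams taxonomy_codes
#' @param code Integer code registered in the taxonomy.
#' @return A list with `code`, `level` (`"main"`, `"subclass"` or
#'   `"disease"`), `name`, and `ancestors` — the integer codes of the
#'   enclosing levels from the top down (empty for a main category).
#' @export
decode_code <- function(taxonomy, code) {
  stopifnot(inherits(taxonomy, "disease_taxonomy"))
  nodes <- taxonomy$nodes
  i <- match(code, nodes$code)
  if (is.na(i)) stop(sprintf("code %s is not registered in the taxonomy", format(code)),
                     call. = FALSE)
  anc <- integer(0)
  p <- nodes$parent_code[i]
  while (!is.na(p)) {
    anc <- c(p, anc)
    p <- nodes$parent_code[match(p, nodes$code)]
  }
  list(code = nodes$code[i], level = nodes$level[i], name = nodes$name[i],
       ancestors = anc)
}

# Fast vectorised ancestor lookup used by the cascade and evaluation code.
# Returns a tibble with columns disease (the input), main_code, subclass_code.
code_ancestry <- function(taxonomy, codes) {
  nodes <- taxonomy$nodes
  i <- match(codes, nodes$code)
  if (anyNA(i)) {
    stop(sprintf("unregistered code(s): %s",
                 paste(unique(codes[is.na(i)]), collapse = ", ")), call. = FALSE)
  }
  if (any(nodes$level[i] != "disease")) {
    stop("all record codes must be specific-disease (leaf) codes", call. = FALSE)
  }
  sub <- nodes$parent_code[i]
  main <- nodes$parent_code[match(sub, nodes$code)]
  tibble::tibble(disease = nodes$code[i], subclass_code = sub, main_code = main)
}

#' Expand case records into the three-level data-relationship list
#'
#' Each raw record (symptom flags plus a specific-disease code) relates to
#' three data items: one at the main-category level, one at the subclass
#' level and one at the disease level, all sharing the record's symptom
#' vector. This is the expansion used to assemble per-level training sets.
#'
#' @param records A data frame with one column per symptom (0/1 flags, in
#'   taxonomy order) and a `disease` column of leaf codes.
#' @inheritParams taxonomy_codes
#' @return A tibble with the symptom columns plus `case` (input row number),
#'   `level` and `code`; exactly three rows per input record, ordered main,
#'   subclass, disease.
#' @export
expand_records <- function(records, taxonomy) {
  records <- validate_records(records, taxonomy)
  anc <- code_ancestry(taxonomy, records$disease)
  sym <- dplyr::select(records, -"disease")
  out <- tibble::tibble(
    case = rep(seq_len(nrow(records)), each = 3L),
    level = rep(c("main", "subclass", "disease"), nrow(records)),
    code = as.vector(rbind(anc$main_code, anc$subclass_code, anc$disease)))
  dplyr::bind_cols(sym[out$case, , drop = FALSE], out)
}

# Shared record validation: column names, binary flags, registered leaf codes.
validate_records <- function(records, taxonomy, what = "records") {
  stopifnot(inherits(taxonomy, "disease_taxonomy"))
  records <- tibble::as_tibble(records)
  expected <- c(taxonomy$symptom_names, "disease")
  if (!identical(names(records), expected)) {
    stop(sprintf("%s must have columns %s (in order); got %s", what,
                 paste(expected, collapse = ", "),
                 paste(names(records), collapse = ", ")), call. = FALSE)
  }
  flags <- as.matrix(records[taxonomy$symptom_names])
  bad <- which(!(flags %in% c(0, 1)))
  if (length(bad) > 0) {
    row <- ((bad[1] - 1) %% nrow(flags)) + 1
    stop(sprintf("non-binary symptom flag in %s row %d", what, row), call. = FALSE)
  }
  invisible(code_ancestry(taxonomy, records$disease))
  records
}

#' Read and write case-record CSV files
#'
#' Records are stored as comma-separated UTF-8 text with a mandatory header:
#' one column per symptom (0/1 literals), in the taxonomy's symptom order,
#' followed by a `disease` column holding the specific-disease integer code.
#'
#' @param path File path.
#' @inheritParams taxonomy_codes
#' @return `read_records()` returns a validated tibble of records;
#'   `write_records()` returns `path` invisibly.
#' @export
read_records <- function(path, taxonomy) {
  stopifnot(inherits(taxonomy, "disease_taxonomy"))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_integer()),
                        progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop(sprintf("parse error in %s at row %d: %s", path, probs$row[1],
                 probs$expected[1]), call. = FALSE)
  }
  validate_records(df, taxonomy, what = basename(path))
}

#' @rdname read_records
#' @param records A data frame of case records.
#' @export
write_records <- function(records, path, taxonomy) {
  records <- validate_records(records, taxonomy)
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read and write taxonomy description files
#'
#' The on-disk format is a JSON tree:
#' `{code_base, symptom_names, categories: [{b, name, subclasses: [{j, name,
#' diseases: [{t, name}]}]}]}`.
#'
#' @param path File path.
#' @return `read_taxonomy()` returns a `disease_taxonomy`; `write_taxonomy()`
#'   returns `path` invisibly.
#' @export
read_taxonomy <- function(path) {
  taxonomy_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

taxonomy_from_list <- function(doc) {
  cats <- lapply(doc$categories, function(cs) {
    list(name = cs$name, subclasses = lapply(cs$subclasses %||% list(), function(ss) {
      list(name = ss$name, diseases = lapply(ss$diseases %||% list(), function(ds) {
        list(name = ds$name)
      }))
    }))
  })
  disease_taxonomy(categories = cats,
                   symptom_names = vapply(doc$symptom_names, as.character, character(1)),
                   code_base = doc$code_base)
}

#' @rdname read_taxonomy
#' @param taxonomy A `disease_taxonomy`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  jsonlite::write_json(taxonomy_as_list(taxonomy), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

taxonomy_as_list <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "disease_taxonomy"))
  nodes <- taxonomy$nodes
  cats <- lapply(which(nodes$level == "main"), function(i) {
    b <- nodes$b[i]
    subs <- lapply(which(nodes$level == "subclass" & nodes$b == b), function(k) {
      j <- nodes$j[k]
      dis <- lapply(which(nodes$level == "disease" & nodes$b == b & nodes$j == j),
                    function(m) list(t = nodes$t[m], name = nodes$name[m]))
      list(j = j, name = nodes$name[k], diseases = dis)
    })
    list(b = b, name = nodes$name[i], subclasses = subs)
  })
  list(code_base = taxonomy$code_base, symptom_names = taxonomy$symptom_names,
       categories = cats)
}
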