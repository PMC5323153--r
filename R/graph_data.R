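#' Association matrix between miRNAs and diseases
#'
#' Constructs the binary adjacency matrix `A` of known miRNA-disease
#' associations: rows are miRNAs, columns are diseases, and `A[i, j] = 1`
#' iff miRNA `i` has a recorded association with disease `j`. Row `i` is the
#' interaction profile of miRNA `i`; column `j` is the interaction profile of
#' disease `j`.
#'
#' @param values Binary numeric matrix (`nm x nd`).
#' @param mirna_ids Character vector of unique miRNA identifiers (length `nm`).
#' @param disease_ids Character vector of unique disease identifiers
#'   (length `nd`).
#' @return An object of class `assoc_matrix`: a list with elements
#'   `mirna_ids`, `disease_ids` and `values` (a dimnamed binary matrix).
#' @seealso [read_associations()], [validate_association_matrix()]
#' @export
association_matrix <- function(values, mirna_ids, disease_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(mirna_ids, disease_ids)
  x <- structure(
    list(mirna_ids = as.character(mirna_ids),
         disease_ids = as.character(disease_ids),
         values = values),
    class = "assoc_matrix"
  )
  validate_association_matrix(x)
  x
}

#' Validate an association matrix
#'
#' Checks the type invariants: entries in \{0, 1\}, identifier lists free of
#' duplicates, and shape agreement between identifiers and matrix.
#'
#' @param x An `assoc_matrix`.
#' @return `x`, invisibly; errors if an invariant is violated.
#' @export
validate_association_matrix <- function(x) {
  stopifnot(inherits(x, "assoc_matrix"))
  if (anyDuplicated(x$mirna_ids)) stop("duplicate miRNA identifiers")
  if (anyDuplicated(x$disease_ids)) stop("duplicate disease identifiers")
  if (nrow(x$values) != length(x$mirna_ids) ||
      ncol(x$values) != length(x$disease_ids)) {
    stop("matrix shape does not match identifier lists")
  }
  if (!all(x$values %in% c(0, 1))) stop("association entries must be 0 or 1")
  invisible(x)
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf(
    "<assoc_matrix> %d miRNAs x %d diseases, %d known associations (density %.4f)\n",
    length(x$mirna_ids), length(x$disease_ids), sum(x$values),
    mean(x$values)
  ))
  invisible(x)
}

#' @method as_tibble assoc_matrix
#' @export
as_tibble.assoc_matrix <- function(x, ...) {
  idx <- which(x$values == 1, arr.ind = TRUE)
  tibble::tibble(
    mirna_id = x$mirna_ids[idx[, 1]],
    disease_id = x$disease_ids[idx[, 2]]
  ) |>
    dplyr::arrange(.data$mirna_id, .data$disease_id)
}

#' Partially observed symmetric similarity matrix
#'
#' Container for a similarity network whose scores cover only some pairs:
#' the miRNA functional-similarity matrix `FS` (precomputed scores rarely
#' cover every miRNA) and the disease semantic-similarity matrix `SS`
#' (diseases missing from the MeSH table have no score). Unobserved pairs
#' later fall back to the Gaussian interaction-profile kernel during
#' integration.
#'
#' @param ids Character vector of identifiers.
#' @param values Symmetric numeric matrix of scores in `[0, 1]`.
#' @param observed Symmetric logical matrix; `TRUE` where a score is known.
#'   The diagonal is always forced observed with value 1.
#' @return An object of class `partial_similarity`.
#' @export
partial_similarity <- function(ids, values, observed) {
  ids <- as.character(ids)
  values <- as.matrix(values)
  observed <- as.matrix(observed)
  diag(values) <- 1
  diag(observed) <- TRUE
  dimnames(values) <- list(ids, ids)
  dimnames(observed) <- list(ids, ids)
  x <- structure(
    list(ids = ids, values = values, observed = observed),
    class = "partial_similarity"
  )
  validate_partial_similarity(x)
  x
}

#' Validate a partial similarity matrix
#'
#' @param x A `partial_similarity`.
#' @return `x`, invisibly; errors if symmetry, range or mask invariants fail.
#' @export
validate_partial_similarity <- function(x) {
  stopifnot(inherits(x, "partial_similarity"))
  n <- length(x$ids)
  if (anyDuplicated(x$ids)) stop("duplicate identifiers")
  if (!all(dim(x$values) == n) || !all(dim(x$observed) == n)) {
    stop("matrix shape does not match identifier list")
  }
  if (!isTRUE(all.equal(x$observed, t(x$observed)))) {
    stop("observation mask must be symmetric")
  }
  obs <- x$observed & t(x$observed)
  if (max(abs(x$values[obs] - t(x$values)[obs])) > 1e-12) {
    stop("similarity values must be symmetric where observed")
  }
  v <- x$values[obs]
  if (any(v < 0 | v > 1)) stop("similarity scores must lie in [0, 1]")
  if (!all(diag(x$observed)) || !all(diag(x$values) == 1)) {
    stop("diagonal must be observed with value 1")
  }
  invisible(x)
}

#' Validate a dense similarity matrix
#'
#' Checks the contract shared by the Gaussian kernels `KD`/`KM` and the
#' integrated similarities `SM`/`SD`: square, symmetric to within 1e-12,
#' unit diagonal, non-negative entries.
#'
#' @param values Numeric matrix.
#' @param unit_diag Require `diag == 1` (set `FALSE` after normalization).
#' @return `values`, invisibly.
#' @export
validate_similarity_matrix <- function(values, unit_diag = TRUE) {
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (max(abs(values - t(values))) > 1e-12) {
    stop("similarity matrix must be symmetric to within 1e-12")
  }
  if (any(values < 0)) stop("similarity entries must be non-negative")
  if (unit_diag && any(abs(diag(values) - 1) > 1e-12)) {
    stop("similarity diagonal must equal 1")
  }
  invisible(values)
}

# -- TSV parsing ------------------------------------------------------------
# Dialect: plain TSV, UTF-8, no quoting; lines starting with '#' are comments.

read_tsv_fields <- function(path, n_fields, what) {
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop(sprintf("empty %s file: %s", what, path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad) > 0) {
    stop(sprintf(
      "malformed %s row at line %d of %s: expected %d tab-separated fields, got %d",
      what, line_no[bad[1]], path, n_fields, lengths(parts)[bad[1]]
    ))
  }
  m <- matrix(unlist(parts), ncol = n_fields, byrow = TRUE)
  m[] <- trimws(m)
  m
}

#' Read known miRNA-disease associations from a two-column TSV
#'
#' Each row names one association (miRNA identifier, disease identifier).
#' Identifiers are ordered by first appearance in the file; duplicate rows are
#' collapsed to a single association with a warning.
#'
#' @param path Path to a tab-separated file with two columns and no header.
#'   `#`-prefixed lines are skipped.
#' @return An [association_matrix()].
#' @export
read_associations <- function(path) {
  m <- read_tsv_fields(path, 2L, "association")
  mirna_ids <- unique(m[, 1])
  disease_ids <- unique(m[, 2])
  key <- paste(m[, 1], m[, 2], sep = "\r")
  n_dup <- sum(duplicated(key))
  if (n_dup > 0) {
    warning(sprintf("%d duplicate association row(s) collapsed", n_dup))
  }
  values <- matrix(0, length(mirna_ids), length(disease_ids))
  values[cbind(match(m[, 1], mirna_ids), match(m[, 2], disease_ids))] <- 1
  association_matrix(values, mirna_ids, disease_ids)
}

#' Read a miRNA functional-similarity score table
#'
#' Reads three-column rows (miRNA, miRNA, score in `[0, 1]`) into a
#' [partial_similarity()] aligned to `mirna_ids`. Pairs absent from the file
#' are unobserved; scores are stored symmetrically; the diagonal is forced
#' observed with value 1. Rows naming miRNAs outside `mirna_ids` are ignored
#' (a count is messaged).
#'
#' @param path Path to a tab-separated file with three columns and no header.
#' @param mirna_ids Ordered identifiers the output is aligned to (normally
#'   the association matrix row order).
#' @return A [partial_similarity()] over `mirna_ids`.
#' @export
read_functional_similarity <- function(path, mirna_ids) {
  n <- length(mirna_ids)
  values <- diag(1, n)
  observed <- diag(n) == 1
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  if (any(keep)) {
    m <- read_tsv_fields(path, 3L, "functional-similarity")
    score <- suppressWarnings(as.numeric(m[, 3]))
    if (anyNA(score)) stop("non-numeric functional-similarity score")
    if (any(score < 0 | score > 1)) {
      stop("functional-similarity scores must lie in [0, 1]")
    }
    i <- match(m[, 1], mirna_ids)
    j <- match(m[, 2], mirna_ids)
    known <- !is.na(i) & !is.na(j)
    n_skip <- sum(!known)
    if (n_skip > 0) {
      message(sprintf(
        "%d functional-similarity row(s) name miRNAs outside the association set; ignored",
        n_skip
      ))
    }
    i <- i[known]; j <- j[known]; score <- score[known]
    # reject the same unordered pair recorded with two different scores
    key <- paste(pmin(i, j), pmax(i, j))
    agg <- tapply(score, key, function(s) length(unique(s)))
    if (any(agg > 1)) {
      stop("conflicting duplicate functional-similarity scores for one pair")
    }
    off <- i != j
    values[cbind(i[off], j[off])] <- score[off]
    values[cbind(j[off], i[off])] <- score[off]
    observed[cbind(i[off], j[off])] <- TRUE
    observed[cbind(j[off], i[off])] <- TRUE
  }
  partial_similarity(mirna_ids, values, observed)
}

mesh_number_pattern <- "^[A-Z][0-9]{2}(\\.[0-9]+)*$"

#' Read MeSH Category-C tree numbers
#'
#' Reads a two-column table (disease term, dotted tree number such as
#' `C04.557.337`). A term may own several tree numbers (one row each); a tree
#' number may belong to only one term.
#'
#' @param path Path to a tab-separated file with two columns and no header.
#' @return A list with `term_numbers` (named list: term -> character vector of
#'   tree numbers) and `number_term` (named character: tree number -> term).
#' @export
read_mesh_tree_numbers <- function(path) {
  m <- read_tsv_fields(path, 2L, "tree-number")
  term <- m[, 1]
  num <- m[, 2]
  bad <- !grepl(mesh_number_pattern, num)
  if (any(bad)) {
    stop(sprintf("malformed tree number '%s' for term '%s'",
                 num[which(bad)[1]], term[which(bad)[1]]))
  }
  dup <- duplicated(num)
  if (any(dup)) {
    owners <- unique(term[num == num[which(dup)[1]]])
    if (length(owners) > 1) {
      stop(sprintf("tree number '%s' assigned to multiple terms",
                   num[which(dup)[1]]))
    }
    keep <- !duplicated(paste(term, num, sep = "\r"))
    term <- term[keep]; num <- num[keep]
    if (anyDuplicated(num)) {
      stop("tree number assigned to multiple terms")
    }
  }
  number_term <- stats::setNames(term, num)
  term_numbers <- split(num, term)[unique(term)]
  list(term_numbers = term_numbers, number_term = number_term)
}

#' Write ranked association predictions
#'
#' Writes one row per still-unknown miRNA-disease pair: disease, miRNA,
#' predicted score, and the miRNA's rank within that disease (descending
#' score, ties broken by miRNA identifier). Pairs already known in `known`
#' are excluded.
#'
#' @param scores A `score_matrix` (see [propagate()]).
#' @param known The [association_matrix()] of known associations.
#' @param path Output TSV path.
#' @return The written tibble, invisibly.
#' @export
write_predictions <- function(scores, known, path) {
  if (!identical(scores$mirna_ids, known$mirna_ids) ||
      !identical(scores$disease_ids, known$disease_ids)) {
    stop("score and association matrices must share identifiers and order")
  }
  out <- tibble::tibble(
    disease = rep(known$disease_ids, each = length(known$mirna_ids)),
    mirna = rep(known$mirna_ids, times = length(known$disease_ids)),
    score = as.vector(scores$values),
    known = as.vector(known$values)
  ) |>
    dplyr::filter(.data$known == 0) |>
    dplyr::select(-"known") |>
    dplyr::arrange(factor(.data$disease, levels = known$disease_ids),
                   dplyr::desc(.data$score), .data$mirna) |>
    dplyr::group_by(.data$disease) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  readr::write_tsv(out, path)
  invisible(out)
}

#' Write an association matrix back to the two-column TSV dialect
#'
#' @param assoc An [association_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  idx <- which(assoc$values == 1, arr.ind = TRUE)
  # preserve first-appearance order: sort by row-major occurrence
  ord <- order(idx[, 1], idx[, 2])
  lines <- paste(assoc$mirna_ids[idx[ord, 1]],
                 assoc$disease_ids[idx[ord, 2]], sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}
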