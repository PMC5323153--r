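#' Semantic and kernel similarity configuration
#'
#' @param delta Semantic contribution factor in (0, 1): the per-edge decay
#'   applied to an ancestor's contribution as it moves away from the disease
#'   at the DAG root. Default 0.5, the convention of the functional-similarity
#'   method this measure derives from.
#' @return A validated list of class `semantic_config`.
#' @export
semantic_config <- function(delta = 0.5) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta >= 1) {
    stop("delta must satisfy 0 < delta < 1")
  }
  structure(list(delta = delta), class = "semantic_config")
}

#' @param gamma_prime_d,gamma_prime_m Raw Gaussian-kernel bandwidths for the
#'   disease and miRNA interaction profiles; both strictly positive. Each is
#'   divided by the mean squared profile norm before use, so 1 (the GIP-kernel
#'   convention) keeps the kernel scale comparable across datasets of
#'   different density.
#' @rdname semantic_config
#' @export
kernel_config <- function(gamma_prime_d = 1, gamma_prime_m = 1) {
  if (gamma_prime_d <= 0 || gamma_prime_m <= 0) {
    stop("raw bandwidths gamma_prime must be strictly positive")
  }
  structure(list(gamma_prime_d = gamma_prime_d, gamma_prime_m = gamma_prime_m),
            class = "kernel_config")
}

#' Build the MeSH ancestor DAG of one disease
#'
#' A disease `D` is represented as `DAG(D) = (D, T(D), E(D))` where `T(D)`
#' holds `D` and all its ancestors and `E(D)` the parent-to-child edges.
#' Ancestors are the terms owning any proper dotted prefix of any of `D`'s
#' tree numbers; prefixes with no owning term are skipped, so each edge joins
#' the nearest indexed ancestor to its descendant. A term with several tree
#' numbers contributes the union of its ancestor paths to a single DAG.
#'
#' @param term Disease term (the DAG root).
#' @param tree_index Named character vector mapping tree number to owning term
#'   (from [read_mesh_tree_numbers()], element `number_term`).
#' @param term_numbers Named list mapping term to its tree numbers (element
#'   `term_numbers`).
#' @return A list of class `disease_dag` with `root`, `nodes` (character) and
#'   `edges` (tibble with columns `parent`, `child`).
#' @export
build_dag <- function(term, tree_index, term_numbers) {
  numbers <- term_numbers[[term]]
  if (is.null(numbers) || length(numbers) == 0) {
    stop(sprintf("term '%s' has no tree numbers", term))
  }
  nodes <- term
  parent <- character(0)
  child <- character(0)
  for (num in numbers) {
    parts <- strsplit(num, ".", fixed = TRUE)[[1]]
    current <- term
    if (length(parts) > 1) {
      for (k in (length(parts) - 1):1) {
        prefix <- paste(parts[1:k], collapse = ".")
        owner <- unname(tree_index[prefix])
        if (!is.na(owner)) {
          if (owner != current) {
            parent <- c(parent, owner)
            child <- c(child, current)
            nodes <- c(nodes, owner)
            current <- owner
          }
        }
      }
    }
  }
  edges <- tibble::tibble(parent = parent, child = child) |> dplyr::distinct()
  structure(
    list(root = term, nodes = unique(nodes), edges = edges),
    class = "disease_dag"
  )
}

#' Semantic contribution of each DAG node
#'
#' The disease at the root contributes 1; every ancestor `d` contributes
#' `max(delta * DD(d'))` over its children `d'` within the DAG, so the
#' contribution decays geometrically with distance from the root disease.
#'
#' @param dag A `disease_dag` from [build_dag()].
#' @param cfg A [semantic_config()].
#' @return Named numeric vector of contributions `DD`, one per node, all in
#'   `(0, 1]`.
#' @export
semantic_contributions <- function(dag, cfg = semantic_config()) {
  delta <- cfg$delta
  dd <- stats::setNames(rep(NA_real_, length(dag$nodes)), dag$nodes)
  compute <- function(node) {
    if (!is.na(dd[[node]])) return(dd[[node]])
    if (node == dag$root) {
      dd[[node]] <<- 1
    } else {
      kids <- dag$edges$child[dag$edges$parent == node]
      dd[[node]] <<- max(vapply(kids, compute, numeric(1))) * delta
    }
    dd[[node]]
  }
  for (node in dag$nodes) compute(node)
  dd
}

#' Semantic value of a disease
#'
#' The sum of the contributions of every node in the disease's DAG; at least
#' 1 because the root always contributes 1.
#'
#' @param dd Named contribution vector from [semantic_contributions()].
#' @return A single number `DV >= 1`.
#' @export
semantic_value <- function(dd) {
  stopifnot(length(dd) >= 1)
  sum(dd)
}

#' Semantic similarity between two diseases
#'
#' Diseases sharing a larger part of their MeSH DAGs score higher:
#' `SS = sum over shared nodes t of (DD_i(t) + DD_j(t)) / (DV_i + DV_j)`,
#' where each contribution is evaluated within that disease's own DAG.
#' Symmetric, 1 for identical DAGs, 0 for disjoint ones.
#'
#' @param dag_i,dag_j `disease_dag` objects.
#' @param cfg A [semantic_config()].
#' @return Similarity score in `[0, 1]`.
#' @export
semantic_similarity <- function(dag_i, dag_j, cfg = semantic_config()) {
  dd_i <- semantic_contributions(dag_i, cfg)
  dd_j <- semantic_contributions(dag_j, cfg)
  shared <- intersect(dag_i$nodes, dag_j$nodes)
  if (length(shared) == 0) return(0)
  sum(dd_i[shared] + dd_j[shared]) / (semantic_value(dd_i) + semantic_value(dd_j))
}

#' Disease semantic-similarity matrix over an identifier list
#'
#' Builds one DAG per disease found in the MeSH table and evaluates all
#' pairwise semantic similarities. Diseases absent from the table (matching is
#' by exact term equality) stay unobserved, so integration falls back to the
#' interaction-profile kernel for them.
#'
#' @param disease_ids Ordered disease identifiers (association matrix order).
#' @param mesh Tree-number mapping from [read_mesh_tree_numbers()].
#' @param cfg A [semantic_config()].
#' @return A [partial_similarity()] over `disease_ids`.
#' @export
semantic_similarity_matrix <- function(disease_ids, mesh,
                                       cfg = semantic_config()) {
  n <- length(disease_ids)
  values <- diag(1, n)
  observed <- diag(n) == 1
  present <- disease_ids %in% names(mesh$term_numbers)
  idx <- which(present)
  dags <- lapply(disease_ids[idx], build_dag,
                 tree_index = mesh$number_term,
                 term_numbers = mesh$term_numbers)
  dds <- lapply(dags, semantic_contributions, cfg = cfg)
  dvs <- vapply(dds, semantic_value, numeric(1))
  if (length(idx) >= 2) {
    for (a in seq_len(length(idx) - 1)) {
      for (b in (a + 1):length(idx)) {
        shared <- intersect(dags[[a]]$nodes, dags[[b]]$nodes)
        ss <- if (length(shared) == 0) 0 else {
          sum(dds[[a]][shared] + dds[[b]][shared]) / (dvs[a] + dvs[b])
        }
        values[idx[a], idx[b]] <- ss
        values[idx[b], idx[a]] <- ss
      }
    }
  }
  observed[idx, idx] <- TRUE
  partial_similarity(disease_ids, values, observed)
}

#' Gaussian interaction-profile kernel bandwidth
#'
#' Normalizes the raw bandwidth by the average squared norm of the binary
#' interaction profiles, i.e. by the mean number of known associations per
#' entity: `gamma = gamma_prime / mean(||IP||^2)`. Denser association
#' matrices therefore get a smaller effective bandwidth.
#'
#' @param profiles Numeric matrix, one binary interaction profile per row.
#' @param gamma_prime Raw bandwidth, strictly positive.
#' @return The effective bandwidth `gamma`.
#' @export
gip_bandwidth <- function(profiles, gamma_prime = 1) {
  stopifnot(nrow(profiles) >= 1, gamma_prime > 0)
  mean_sq <- mean(rowSums(profiles^2))
  if (mean_sq == 0) {
    stop("bandwidth undefined: every interaction profile is all-zero")
  }
  gamma_prime / mean_sq
}

#' Gaussian interaction-profile kernel matrix
#'
#' `K(u, v) = exp(-gamma * ||IP(u) - IP(v)||^2)`: symmetric, unit diagonal,
#' entries in (0, 1]. Used on the rows of the association matrix for miRNAs
#' (`KM`) and on its columns for diseases (`KD`).
#'
#' @param profiles Numeric matrix, one interaction profile per row.
#' @param gamma Effective bandwidth from [gip_bandwidth()], positive.
#' @return A dense symmetric similarity matrix with the profiles' rownames.
#' @export
gip_kernel <- function(profiles, gamma) {
  stopifnot(gamma > 0)
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  k <- exp(-gamma * d2)
  k <- (k + t(k)) / 2
  diag(k) <- 1
  dimnames(k) <- list(rownames(profiles), rownames(profiles))
  k
}

#' Integrate kernel similarity with functional/semantic scores
#'
#' Where a functional (miRNA side) or semantic (disease side) score is
#' observed, the integrated similarity is the average of that score and the
#' Gaussian interaction-profile kernel; elsewhere it is the kernel alone.
#' This fallback is what lets the method score diseases and miRNAs missing
#' from the curated similarity tables.
#'
#' @param kernel Dense kernel similarity matrix (`KD` or `KM`).
#' @param partial A [partial_similarity()] with the same identifiers/order.
#' @return A dense symmetric similarity matrix (`SM` or `SD`).
#' @export
integrate_similarity <- function(kernel, partial) {
  if (!is.null(rownames(kernel)) &&
      !identical(rownames(kernel), partial$ids)) {
    stop("kernel and partial similarity identifiers do not match")
  }
  if (nrow(kernel) != length(partial$ids)) {
    stop("kernel and partial similarity dimensions do not match")
  }
  out <- kernel
  obs <- partial$observed
  out[obs] <- (kernel[obs] + partial$values[obs]) / 2
  diag(out) <- 1
  out
}
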