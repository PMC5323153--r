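#' Propagation configuration
#'
#' @param alpha Decay factor in `[0, 1)`: the weight of propagated network
#'   evidence versus the prior association matrix at each iteration, playing
#'   the role of a restart probability. Default 0.4, following the
#'   heterogeneous-graph-inference precedent the method mirrors.
#' @param tol Convergence cutoff on the elementwise L1 norm of the change
#'   between successive score matrices. Default `1e-6`.
#' @param max_iter Iteration cap. Default 10000.
#' @return A validated list of class `propagation_config`.
#' @export
propagation_config <- function(alpha = 0.4, tol = 1e-6, max_iter = 10000L) {
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    stop("alpha must satisfy 0 <= alpha < 1")
  }
  if (tol <= 0) stop("tol must be positive")
  if (max_iter < 1) stop("max_iter must be at least 1")
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter)),
            class = "propagation_config")
}

#' Symmetric normalization of a similarity network
#'
#' Divides each entry by the square root of the product of its row and
#' column sums: `out(i, j) = sim(i, j) / sqrt(rowsum_i * rowsum_j)`. For a
#' symmetric non-negative matrix with positive row sums the result is
#' similar to a row-stochastic matrix, so its spectral radius is at most 1
#' and the two-sided propagation contracts for any decay factor below 1.
#'
#' @param sim Dense symmetric similarity matrix with positive row sums
#'   (guaranteed by a unit diagonal).
#' @return The normalized matrix (diagonal no longer 1).
#' @export
normalize_similarity <- function(sim) {
  rs <- rowSums(sim)
  if (any(rs <= 0)) stop("normalization requires strictly positive row sums")
  sim / sqrt(outer(rs, rs))
}

new_score_matrix <- function(values, mirna_ids, disease_ids,
                             iterations = 0L, converged = TRUE) {
  dimnames(values) <- list(mirna_ids, disease_ids)
  structure(
    list(mirna_ids = mirna_ids, disease_ids = disease_ids, values = values,
         iterations = as.integer(iterations), converged = converged),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf(
    "<score_matrix> %d miRNAs x %d diseases; %d iteration(s), converged: %s\n",
    length(x$mirna_ids), length(x$disease_ids), x$iterations, x$converged
  ))
  invisible(x)
}

#' @method as_tibble score_matrix
#' @export
as_tibble.score_matrix <- function(x, ...) {
  tibble::tibble(
    mirna_id = rep(x$mirna_ids, times = length(x$disease_ids)),
    disease_id = rep(x$disease_ids, each = length(x$mirna_ids)),
    score = as.vector(x$values)
  )
}

#' One-step path-sum association scores
#'
#' Scores each miRNA-disease pair by summing over all length-three paths
#' miRNA -> similar miRNA -> known association -> similar disease:
#' `P(m, d) = sum_i sum_j SM(m(i), m) * A(m(i), d(j)) * SD(d(j), d)`,
#' which is the triple matrix product `SM A SD`.
#'
#' @param SM miRNA similarity matrix (`nm x nm`).
#' @param A An [association_matrix()].
#' @param SD Disease similarity matrix (`nd x nd`).
#' @return A `score_matrix` (iterations = 1).
#' @export
one_step_scores <- function(SM, A, SD) {
  if (nrow(SM) != nrow(A$values) || ncol(SD) != ncol(A$values)) {
    stop("similarity and association matrix shapes do not conform")
  }
  new_score_matrix(SM %*% A$values %*% SD, A$mirna_ids, A$disease_ids,
                   iterations = 1L)
}

#' Iterate the heterogeneous-graph propagation to its fixed point
#'
#' Starting from `P(0) = A`, iterates
#' `P(i+1) = alpha * SMn P(i) SDn + (1 - alpha) * A` until the elementwise
#' L1 norm of the change drops below `tol`. With both similarity networks
#' symmetrically normalized the map is a contraction for `alpha < 1`, so the
#' fixed point is unique and independent of the start.
#'
#' @param SMn,SDn Similarity matrices normalized by [normalize_similarity()].
#' @param A An [association_matrix()].
#' @param cfg A [propagation_config()].
#' @return A `score_matrix` with `iterations` and `converged` set. Hitting
#'   `max_iter` without convergence returns `converged = FALSE` with a
#'   warning rather than an error.
#' @export
propagate <- function(SMn, SDn, A, cfg = propagation_config()) {
  if (nrow(SMn) != nrow(A$values) || ncol(SDn) != ncol(A$values)) {
    stop("similarity and association matrix shapes do not conform")
  }
  alpha <- cfg$alpha
  P <- A$values
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    P_new <- alpha * (SMn %*% P %*% SDn) + (1 - alpha) * A$values
    iter <- iter + 1L
    if (sum(abs(P_new - P)) < cfg$tol) {
      P <- P_new
      converged <- TRUE
      break
    }
    P <- P_new
  }
  if (!converged) {
    warning(sprintf("propagation did not converge within %d iterations",
                    cfg$max_iter))
  }
  new_score_matrix(P, A$mirna_ids, A$disease_ids, iter, converged)
}

#' Closed-form fixed point of the propagation (linear-solve oracle)
#'
#' Solves the stationarity condition `P = alpha * SMn P SDn + (1 - alpha) A`
#' exactly by flattening to the linear system
#' `(I - alpha * (SDn' \%x\% SMn)) vec(P) = (1 - alpha) vec(A)`.
#' The solution is unique because the propagation operator's spectral radius
#' is at most `alpha < 1`. Intended as an independent oracle for
#' [propagate()] on small problems (the Kronecker system is dense).
#'
#' @inheritParams propagate
#' @param alpha Decay factor in `[0, 1)`.
#' @return A `score_matrix` holding the exact fixed point.
#' @export
closed_form_fixed_point <- function(SMn, SDn, A, alpha) {
  stopifnot(alpha >= 0, alpha < 1)
  nm <- nrow(A$values)
  nd <- ncol(A$values)
  if (nm * nd > 4000) stop("closed-form oracle limited to small systems")
  lhs <- diag(nm * nd) - alpha * (t(SDn) %x% SMn)
  p <- solve(lhs, (1 - alpha) * as.vector(A$values))
  new_score_matrix(matrix(p, nm, nd), A$mirna_ids, A$disease_ids)
}

build_similarities <- function(A, fs = NULL, ss = NULL,
                               ker_cfg = kernel_config()) {
  gm <- tryCatch(
    gip_bandwidth(A$values, ker_cfg$gamma_prime_m),
    error = function(e) {
      message("all miRNA profiles empty; falling back to gamma = gamma_prime")
      ker_cfg$gamma_prime_m
    }
  )
  gd <- tryCatch(
    gip_bandwidth(t(A$values), ker_cfg$gamma_prime_d),
    error = function(e) {
      message("all disease profiles empty; falling back to gamma = gamma_prime")
      ker_cfg$gamma_prime_d
    }
  )
  KM <- gip_kernel(A$values, gm)
  KD <- gip_kernel(t(A$values), gd)
  SM <- if (is.null(fs)) KM else integrate_similarity(KM, fs)
  SD <- if (is.null(ss)) KD else integrate_similarity(KD, ss)
  list(SM = SM, SD = SD)
}

#' Fit the full heterogeneous-graph association model
#'
#' Runs the complete pipeline on an association matrix: Gaussian
#' interaction-profile kernels on both sides, integration with the
#' functional (miRNA) and semantic (disease) similarities where observed,
#' symmetric normalization, and propagation to the fixed point.
#'
#' @param A An [association_matrix()].
#' @param fs Optional [partial_similarity()] of miRNA functional scores.
#' @param ss Optional [partial_similarity()] of disease semantic scores.
#' @param prop_cfg A [propagation_config()].
#' @param ker_cfg A [kernel_config()].
#' @return An object of class `hgimda_fit` with elements `scores` (a
#'   `score_matrix`), `A`, the integrated similarities `SM`/`SD`, and the
#'   configurations used. Supports [generics::tidy()], [generics::glance()]
#'   and [write_predictions()].
#' @examples
#' sim <- simulate_block_dataset(block_model_params(
#'   nm = 20, nd = 12, n_blocks = 2, seed = 7))
#' fit <- hgimda_fit(sim$assoc, sim$fs, sim$ss)
#' dplyr::slice_max(tidy(fit), score, n = 3)
#' @export
hgimda_fit <- function(A, fs = NULL, ss = NULL,
                       prop_cfg = propagation_config(),
                       ker_cfg = kernel_config()) {
  validate_association_matrix(A)
  nets <- build_similarities(A, fs, ss, ker_cfg)
  scores <- propagate(normalize_similarity(nets$SM),
                      normalize_similarity(nets$SD), A, prop_cfg)
  structure(
    list(scores = scores, A = A, SM = nets$SM, SD = nets$SD,
         prop_cfg = prop_cfg, ker_cfg = ker_cfg),
    class = "hgimda_fit"
  )
}

#' @export
print.hgimda_fit <- function(x, ...) {
  cat(sprintf(
    "<hgimda_fit> %d miRNAs x %d diseases, %d known associations\n",
    length(x$A$mirna_ids), length(x$A$disease_ids), sum(x$A$values)
  ))
  cat(sprintf("  alpha = %g, converged in %d iteration(s)\n",
              x$prop_cfg$alpha, x$scores$iterations))
  invisible(x)
}

#' Tidy the fitted association scores
#'
#' @param x An `hgimda_fit`.
#' @param ... Unused.
#' @return A tibble with one row per miRNA-disease pair: `mirna_id`,
#'   `disease_id`, `score`, and `known` (1 for training associations).
#' @method tidy hgimda_fit
#' @export
tidy.hgimda_fit <- function(x, ...) {
  as_tibble(x$scores) |>
    dplyr::mutate(known = as.vector(x$A$values))
}

#' One-row model summary
#'
#' @param x An `hgimda_fit`.
#' @param ... Unused.
#' @return A one-row tibble: problem size, association count, decay factor,
#'   iterations to convergence, convergence flag.
#' @method glance hgimda_fit
#' @export
glance.hgimda_fit <- function(x, ...) {
  tibble::tibble(
    n_mirna = length(x$A$mirna_ids),
    n_disease = length(x$A$disease_ids),
    n_known = sum(x$A$values),
    alpha = x$prop_cfg$alpha,
    tol = x$prop_cfg$tol,
    iterations = x$scores$iterations,
    converged = x$scores$converged
  )
}
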