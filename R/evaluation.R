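#' Leave-one-out cross-validation over known associations
#'
#' Each known association is held out in turn: its entry of `A` is set to 0,
#' the interaction-profile kernels, integrated similarities, normalization
#' and propagation are recomputed on the training matrix (they all depend on
#' `A`, so skipping this would leak the held-out edge), every pair is scored,
#' and the held-out pair is ranked by descending score (average rank under
#' ties) among its candidate set:
#'
#' * `global`: all miRNA-disease pairs without a known association in the
#'   training matrix;
#' * `local`: all miRNAs without a known association with the held-out
#'   disease.
#'
#' The functional and semantic similarities are taken as given — they do not
#' depend on `A` and are computed once outside the folds.
#'
#' @param A An [association_matrix()] with at least 2 known associations.
#' @param fs,ss Optional [partial_similarity()] inputs for the miRNA and
#'   disease sides.
#' @param mode `"global"` or `"local"` candidate sets.
#' @param sem_cfg A [semantic_config()] (carried for provenance; the semantic
#'   matrix itself arrives via `ss`).
#' @param ker_cfg A [kernel_config()].
#' @param prop_cfg A [propagation_config()].
#' @param reuse_kernels If `TRUE`, compute the kernels and normalized
#'   networks once from the full matrix and reuse them across folds. This
#'   leaks one known edge into each fold's similarity and is offered only as
#'   a clearly-labelled cheaper variant for exploration; the default
#'   recomputes per fold.
#' @param scorer Optional replacement scoring function taking the training
#'   [association_matrix()] and returning an `nm x nd` numeric score matrix.
#'   Used to decouple ranking mechanics from the model in tests.
#' @return A tibble of rank records, one row per fold: `mirna_id`,
#'   `disease_id`, `score`, `rank`, `n_candidates`, `mode`. Ranks satisfy
#'   `1 <= rank <= n_candidates + 1`.
#' @export
loocv <- function(A, fs = NULL, ss = NULL,
                  mode = c("global", "local"),
                  sem_cfg = semantic_config(),
                  ker_cfg = kernel_config(),
                  prop_cfg = propagation_config(),
                  reuse_kernels = FALSE,
                  scorer = NULL) {
  mode <- match.arg(mode)
  validate_association_matrix(A)
  if (sum(A$values) < 2) stop("LOOCV needs at least 2 known associations")
  if (is.null(scorer)) {
    if (reuse_kernels) {
      nets <- build_similarities(A, fs, ss, ker_cfg)
      SMn <- normalize_similarity(nets$SM)
      SDn <- normalize_similarity(nets$SD)
      scorer <- function(train) propagate(SMn, SDn, train, prop_cfg)$values
    } else {
      scorer <- function(train) {
        nets <- build_similarities(train, fs, ss, ker_cfg)
        propagate(normalize_similarity(nets$SM),
                  normalize_similarity(nets$SD), train, prop_cfg)$values
      }
    }
  }
  known <- which(A$values == 1, arr.ind = TRUE)
  train <- A
  records <- vector("list", nrow(known))
  for (f in seq_len(nrow(known))) {
    i <- known[f, 1]
    j <- known[f, 2]
    train$values[i, j] <- 0
    P <- scorer(train)
    if (mode == "global") {
      cand <- train$values == 0 # includes the held-out pair
      scores <- P[cand]
      test_pos <- which(which(cand) == ((j - 1) * nrow(P) + i))
    } else {
      cand <- train$values[, j] == 0
      scores <- P[cand, j]
      test_pos <- which(which(cand) == i)
    }
    rk <- unname(rank(-scores, ties.method = "average")[test_pos])
    records[[f]] <- tibble::tibble(
      mirna_id = A$mirna_ids[i],
      disease_id = A$disease_ids[j],
      score = P[i, j],
      rank = rk,
      n_candidates = length(scores) - 1L,
      mode = mode
    )
    train$values[i, j] <- 1
  }
  dplyr::bind_rows(records)
}

#' ROC curve from LOOCV rank records
#'
#' For each held-out association the fraction of candidate negatives ranked
#' above it is `f = (rank - 1) / n_candidates` (average ranks fold ties in as
#' half-beaten). Sweeping a rank-percentile threshold `theta`, sensitivity is
#' the fraction of test samples with `f <= theta` and the false positive rate
#' is `theta` itself (the expected fraction of negatives above a threshold is
#' the percentile). Percentile thresholds make global and local curves
#' comparable despite their very different candidate-set sizes. The AUC of
#' the resulting step curve equals the Mann-Whitney statistic
#' `mean((n_candidates - (rank - 1)) / n_candidates)`.
#'
#' @param records Tibble of rank records from [loocv()].
#' @return An object of class `hgimda_roc`: list with `points` (tibble of
#'   `fpr`, `tpr` from (0,0) to (1,1)) and `auc`.
#' @export
roc_points <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("cannot build a ROC curve from an empty record list")
  }
  stopifnot(all(records$rank >= 1),
            all(records$rank <= records$n_candidates + 1))
  # a fold with no competing negatives beats nothing and loses to nothing
  f <- ifelse(records$n_candidates == 0, 0,
              (records$rank - 1) / records$n_candidates)
  u <- sort(unique(f))
  fpr <- 0
  tpr <- 0
  for (v in u) {
    below <- mean(f < v)
    at <- mean(f <= v)
    if (v > fpr[length(fpr)] || below > tpr[length(tpr)]) {
      fpr <- c(fpr, v)
      tpr <- c(tpr, below)
    }
    fpr <- c(fpr, v)
    tpr <- c(tpr, at)
  }
  if (fpr[length(fpr)] < 1 || tpr[length(tpr)] < 1) {
    fpr <- c(fpr, 1)
    tpr <- c(tpr, 1)
  }
  curve <- structure(
    list(points = tibble::tibble(fpr = fpr, tpr = tpr), auc = NA_real_),
    class = "hgimda_roc"
  )
  curve$auc <- auc(curve)
  curve
}

#' Area under a ROC curve
#'
#' @param curve An `hgimda_roc` (or any object with a `points` tibble of
#'   `fpr`, `tpr` pairs).
#' @param ... Unused.
#' @return Trapezoidal area in `[0, 1]`.
#' @export
auc <- function(curve, ...) UseMethod("auc")

#' @rdname auc
#' @export
auc.hgimda_roc <- function(curve, ...) {
  x <- curve$points$fpr
  y <- curve$points$tpr
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.hgimda_roc <- function(x, ...) {
  cat(sprintf("<hgimda_roc> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @method autoplot hgimda_roc
#' @export
autoplot.hgimda_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path(colour = "#2166AC", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate",
      y = "True positive rate (sensitivity)",
      title = sprintf("LOOCV ROC, AUC = %.4f", object$auc)
    ) +
    ggplot2::theme_minimal()
}
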