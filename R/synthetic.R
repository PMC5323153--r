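#' Parameters of the planted block model
#'
#' The generator emulates the statistical structure the predictor relies on:
#' miRNAs with similar functions associate with similar diseases. miRNAs and
#' diseases are assigned to `n_blocks` latent groups; associations are denser
#' inside matched groups, and both similarity networks concentrate around a
#' high mean within groups and a low mean between them.
#'
#' @param nm,nd Number of miRNAs and diseases.
#' @param n_blocks Number of latent groups `B` (round-robin assignment, for
#'   reproducible balanced blocks).
#' @param p_in,p_out Association probability when the miRNA and disease
#'   groups match / differ; `0 <= p_out < p_in <= 1`.
#' @param s_in,s_out Mean similarity within / between groups;
#'   `0 <= s_out < s_in <= 1`.
#' @param sim_noise Standard deviation of the Gaussian perturbation applied
#'   to similarity scores before clipping to `[0, 1]`.
#' @param fs_coverage Fraction of miRNA pairs with an observed functional
#'   similarity score (emulating the partial coverage of curated scores).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A validated list of class `block_model_params`.
#' @export
block_model_params <- function(nm = 60, nd = 40, n_blocks = 4,
                               p_in = 0.3, p_out = 0.02,
                               s_in = 0.8, s_out = 0.1,
                               sim_noise = 0.05, fs_coverage = 0.7,
                               seed = 1L) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  if (!(s_out >= 0 && s_out < s_in && s_in <= 1)) {
    stop("need 0 <= s_out < s_in <= 1")
  }
  if (fs_coverage < 0 || fs_coverage > 1) stop("fs_coverage must be in [0, 1]")
  if (n_blocks < 1 || nm < n_blocks || nd < n_blocks) {
    stop("need nm, nd >= n_blocks >= 1")
  }
  if (sim_noise < 0) stop("sim_noise must be non-negative")
  structure(
    list(nm = as.integer(nm), nd = as.integer(nd),
         n_blocks = as.integer(n_blocks),
         p_in = p_in, p_out = p_out, s_in = s_in, s_out = s_out,
         sim_noise = sim_noise, fs_coverage = fs_coverage,
         seed = as.integer(seed)),
    class = "block_model_params"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sym_similarity_draw <- function(n, groups, s_in, s_out, noise) {
  mu <- ifelse(outer(groups, groups, "=="), s_in, s_out)
  pert <- matrix(stats::rnorm(n * n, 0, noise), n, n)
  pert[lower.tri(pert)] <- t(pert)[lower.tri(pert)]
  v <- pmin(pmax(mu + pert, 0), 1)
  diag(v) <- 1
  v
}

#' Simulate a block-structured miRNA-disease dataset
#'
#' Draws an association matrix with planted group structure together with
#' partially observed miRNA and disease similarity networks correlated with
#' the same groups, so every pipeline stage can be exercised without
#' external database downloads.
#'
#' @param params A [block_model_params()].
#' @return A list: `assoc` ([association_matrix()]), `fs` (miRNA
#'   [partial_similarity()], coverage `fs_coverage`), `ss` (disease
#'   [partial_similarity()], fully observed), `mirna_groups`,
#'   `disease_groups` (integer ground-truth labels).
#' @export
simulate_block_dataset <- function(params) {
  stopifnot(inherits(params, "block_model_params"))
  p <- params
  with_seed(p$seed, {
    mg <- rep_len(seq_len(p$n_blocks), p$nm)
    dg <- rep_len(seq_len(p$n_blocks), p$nd)
    prob <- ifelse(outer(mg, dg, "=="), p$p_in, p$p_out)
    A <- matrix(stats::rbinom(p$nm * p$nd, 1, as.vector(prob)), p$nm, p$nd)
    assoc <- association_matrix(
      A,
      sprintf("mir%03d", seq_len(p$nm)),
      sprintf("disease%03d", seq_len(p$nd))
    )
    fs_values <- sym_similarity_draw(p$nm, mg, p$s_in, p$s_out, p$sim_noise)
    ss_values <- sym_similarity_draw(p$nd, dg, p$s_in, p$s_out, p$sim_noise)
    pairs <- which(upper.tri(fs_values), arr.ind = TRUE)
    n_obs <- round(p$fs_coverage * nrow(pairs))
    picked <- pairs[sample.int(nrow(pairs), n_obs), , drop = FALSE]
    fs_obs <- diag(p$nm) == 1
    fs_obs[picked] <- TRUE
    fs_obs[picked[, c(2, 1), drop = FALSE]] <- TRUE
    list(
      assoc = assoc,
      fs = partial_similarity(assoc$mirna_ids, fs_values, fs_obs),
      ss = partial_similarity(assoc$disease_ids, ss_values,
                              matrix(TRUE, p$nd, p$nd)),
      mirna_groups = mg,
      disease_groups = dg
    )
  })
}

#' Simulate a MeSH-style tree-number forest
#'
#' Builds one tree per block, rooted at `C01`, `C02`, ..., each root owned by
#' a dedicated non-disease term, and places every disease at a random node of
#' its block's tree via a dotted tree number. Same-block diseases therefore
#' share at least the root ancestor term; cross-block diseases share no node,
#' so their semantic similarity is exactly 0. Output parses with
#' [read_mesh_tree_numbers()].
#'
#' @param n_diseases Number of disease terms (named `disease001`, ...,
#'   matching [simulate_block_dataset()] with round-robin blocks).
#' @param n_blocks Number of trees.
#' @param depth Maximum number of segments below the root.
#' @param seed Integer seed.
#' @return A tibble with columns `term` and `tree_number`, one row per
#'   assignment.
#' @export
simulate_dag_forest <- function(n_diseases, n_blocks = 2, depth = 3,
                                seed = 1L) {
  stopifnot(n_diseases >= 1, n_blocks >= 1, depth >= 1)
  segments <- sprintf("%03d", c(100, 200, 300))
  with_seed(seed, {
    used <- character(0)
    term <- character(0)
    number <- character(0)
    for (b in seq_len(n_blocks)) {
      root <- sprintf("C%02d", b)
      term <- c(term, sprintf("root_%02d", b))
      number <- c(number, root)
      used <- c(used, root)
    }
    blocks <- rep_len(seq_len(n_blocks), n_diseases)
    for (i in seq_len(n_diseases)) {
      root <- sprintf("C%02d", blocks[i])
      k <- sample.int(depth, 1)
      num <- paste(c(root, sample(segments, k, replace = TRUE)),
                   collapse = ".")
      while (num %in% used) {
        num <- paste(c(num, sample(segments, 1)), collapse = ".")
      }
      used <- c(used, num)
      term <- c(term, sprintf("disease%03d", i))
      number <- c(number, num)
    }
    tibble::tibble(term = term, tree_number = number)
  })
}

#' Shuffle the entries of an association matrix
#'
#' Permutes the positions of the 1-entries uniformly at random while keeping
#' the total association count, destroying the alignment between the
#' association pattern and the similarity networks. Used as the signal-free
#' control in the end-to-end evaluation.
#'
#' @param assoc An [association_matrix()].
#' @param seed Integer seed.
#' @return A new [association_matrix()] with the same identifiers and
#'   density.
#' @export
shuffle_associations <- function(assoc, seed = 1L) {
  with_seed(seed, {
    v <- as.vector(assoc$values)
    shuffled <- matrix(sample(v), nrow(assoc$values), ncol(assoc$values))
    association_matrix(shuffled, assoc$mirna_ids, assoc$disease_ids)
  })
}

#' Write a simulated dataset as the standard TSV inputs
#'
#' Writes `associations.tsv` (two columns), `functional_similarity.tsv`
#' (three columns, observed off-diagonal pairs only, upper triangle) and,
#' when a forest is supplied, `tree_numbers.tsv` — the formats the readers
#' and the command-line interface consume.
#'
#' @param dataset Output of [simulate_block_dataset()].
#' @param dir Output directory (created if missing).
#' @param forest Optional tibble from [simulate_dag_forest()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir, forest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(associations = file.path(dir, "associations.tsv"))
  write_associations(dataset$assoc, paths[["associations"]])
  fs <- dataset$fs
  obs <- which(fs$observed & upper.tri(fs$observed), arr.ind = TRUE)
  fs_path <- file.path(dir, "functional_similarity.tsv")
  readr::write_lines(
    sprintf("%s\t%s\t%.6f",
            fs$ids[obs[, 1]], fs$ids[obs[, 2]],
            fs$values[obs]),
    fs_path
  )
  paths[["functional_similarity"]] <- fs_path
  if (!is.null(forest)) {
    tn_path <- file.path(dir, "tree_numbers.tsv")
    readr::write_lines(paste(forest$term, forest$tree_number, sep = "\t"),
                       tn_path)
    paths[["tree_numbers"]] <- tn_path
  }
  invisible(paths)
}
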