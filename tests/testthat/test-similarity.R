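test_that("build_dag collects nearest indexed ancestors", {
  mesh <- read_mesh_tree_numbers(write_tsv_lines("Neoplasms\tC04"))
  dag <- build_dag("Neoplasms", mesh$number_term, mesh$term_numbers)
  expect_identical(dag$nodes, "Neoplasms")
  expect_equal(nrow(dag$edges), 0)

  mesh2 <- read_mesh_tree_numbers(write_tsv_lines(c("A\tC04", "B\tC04.557")))
  dag2 <- build_dag("B", mesh2$number_term, mesh2$term_numbers)
  expect_setequal(dag2$nodes, c("A", "B"))
  expect_equal(dag2$edges, tibble::tibble(parent = "A", child = "B"))

  # unindexed intermediate prefix C04.557 is skipped: edge joins A directly
  mesh3 <- read_mesh_tree_numbers(write_tsv_lines(c(
    "A\tC04", "B\tC04.557.100")))
  dag3 <- build_dag("B", mesh3$number_term, mesh3$term_numbers)
  expect_equal(dag3$edges, tibble::tibble(parent = "A", child = "B"))

  # multiple tree numbers merge into one DAG rooted at the focal term
  mesh4 <- read_mesh_tree_numbers(write_tsv_lines(c(
    "CA\tC04", "CB\tC06", "C\tC04.100", "C\tC06.200")))
  dag4 <- build_dag("C", mesh4$number_term, mesh4$term_numbers)
  expect_setequal(dag4$nodes, c("C", "CA", "CB"))
  expect_equal(nrow(dag4$edges), 2)
  expect_setequal(dag4$edges$child, c("C", "C"))

  expect_error(build_dag("missing", mesh$number_term, mesh$term_numbers),
               "no tree numbers")
})

test_that("semantic contributions decay geometrically from the root disease", {
  mesh <- read_mesh_tree_numbers(write_tsv_lines(c(
    "G\tC04", "P\tC04.100", "D\tC04.100.200")))
  dag <- build_dag("D", mesh$number_term, mesh$term_numbers)
  dd <- semantic_contributions(dag, semantic_config(0.5))
  expect_equal(dd[["D"]], 1)
  expect_equal(dd[["P"]], 0.5)
  expect_equal(dd[["G"]], 0.25)
  expect_equal(semantic_value(dd), 1.75)

  single <- build_dag("G", mesh$number_term, mesh$term_numbers)
  expect_equal(semantic_contributions(single), c(G = 1))
  expect_equal(semantic_value(c(root = 1)), 1)
})

test_that("a node with several children takes the maximum contribution", {
  # X is an ancestor of D along two paths: directly (X -> D) and through P,
  # so its children in the DAG are D (DD = 1) and P (DD = 0.5)
  mesh <- read_mesh_tree_numbers(write_tsv_lines(c(
    "X\tC04", "P\tC04.100", "D\tC04.100.200", "D\tC04.300")))
  dag <- build_dag("D", mesh$number_term, mesh$term_numbers)
  dd <- semantic_contributions(dag, semantic_config(0.5))
  expect_equal(dd[["X"]], max(0.5 * 1, 0.5 * 0.5))
})

test_that("semantic similarity matches the hand-worked sibling example", {
  mesh <- sibling_mesh()
  dag1 <- build_dag("D1", mesh$number_term, mesh$term_numbers)
  dag2 <- build_dag("D2", mesh$number_term, mesh$term_numbers)
  cfg <- semantic_config(0.5)
  # shared part {P, G}: (0.5 + 0.25) * 2 / (1.75 + 1.75) = 3/7
  expect_equal(semantic_similarity(dag1, dag2, cfg), 3 / 7,
               tolerance = 1e-12)
  expect_equal(semantic_similarity(dag1, dag2, cfg),
               semantic_similarity(dag2, dag1, cfg))
  # identical DAGs
  expect_identical(semantic_similarity(dag1, dag1, cfg), 1)
  # disjoint trees
  mesh_far <- read_mesh_tree_numbers(write_tsv_lines(c("Z\tC09")))
  dagz <- build_dag("Z", mesh_far$number_term, mesh_far$term_numbers)
  expect_identical(semantic_similarity(dag1, dagz, cfg), 0)
})

test_that("self-similarity is exactly 1 on randomly grown DAGs", {
  for (seed in 1:10) {
    rm_ <- random_mesh(8, seed)
    for (term in sample(rm_$terms, 5)) {
      dag <- build_dag(term, rm_$mesh$number_term, rm_$mesh$term_numbers)
      expect_identical(semantic_similarity(dag, dag), 1)
    }
  }
})

test_that("adding a shared ancestor never decreases semantic similarity", {
  # grow a random tree; compare SS before and after indexing one more shared
  # ancestor term against a direct re-evaluation on the enlarged DAGs
  for (seed in 1:10) {
    set.seed(seed)
    # chain C01 -> C01.5 -> C01.5.5 with two siblings below
    base <- c("tA\tC01.5.5.1", "tB\tC01.5.5.2", "mid\tC01.5.5")
    mesh_small <- read_mesh_tree_numbers(write_tsv_lines(base))
    mesh_big <- read_mesh_tree_numbers(write_tsv_lines(c(base, "top\tC01.5")))
    ss_small <- semantic_similarity(
      build_dag("tA", mesh_small$number_term, mesh_small$term_numbers),
      build_dag("tB", mesh_small$number_term, mesh_small$term_numbers))
    ss_big <- semantic_similarity(
      build_dag("tA", mesh_big$number_term, mesh_big$term_numbers),
      build_dag("tB", mesh_big$number_term, mesh_big$term_numbers))
    expect_gte(ss_big, ss_small)
  }
})

test_that("gip_bandwidth normalizes by the mean squared profile norm", {
  expect_equal(gip_bandwidth(rbind(c(1, 0), c(0, 1)), 1), 1)
  expect_equal(gip_bandwidth(rbind(c(1, 1), c(1, 1)), 2), 1)
  expect_error(gip_bandwidth(matrix(0, 2, 2), 1), "all-zero")
})

test_that("gip_kernel matches hand-computed Gaussian values", {
  k <- gip_kernel(rbind(c(1, 0), c(0, 1)), 1)
  expect_equal(k[1, 2], exp(-2), tolerance = 1e-12)
  expect_equal(diag(k), c(1, 1), ignore_attr = TRUE)

  k2 <- gip_kernel(rbind(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(k2[1, 2], exp(-1), tolerance = 1e-12)

  # identical profiles are maximally similar everywhere
  k3 <- gip_kernel(rbind(c(1, 0, 1), c(1, 0, 1)), 2)
  expect_true(all(k3 == 1))
})

test_that("gip_kernel is invariant under coordinate permutation", {
  set.seed(3)
  profiles <- matrix(rbinom(40, 1, 0.4), 5, 8)
  gamma <- gip_bandwidth(profiles, 1)
  perm <- sample(8)
  expect_equal(gip_kernel(profiles, gamma),
               gip_kernel(profiles[, perm], gamma))
})

test_that("denser association profiles shrink the effective bandwidth", {
  set.seed(4)
  sparse <- matrix(rbinom(60, 1, 0.2), 6, 10)
  dense <- pmax(sparse, matrix(rbinom(60, 1, 0.5), 6, 10))
  expect_lt(gip_bandwidth(dense, 1), gip_bandwidth(sparse, 1))
})

test_that("integration averages where observed and falls back to the kernel", {
  ids <- c("a", "b", "c")
  kernel <- matrix(c(1, 0.8, 0.3,
                     0.8, 1, 0.5,
                     0.3, 0.5, 1), 3, byrow = TRUE,
                   dimnames = list(ids, ids))
  values <- diag(3)
  values[1, 2] <- values[2, 1] <- 0.6
  observed <- diag(3) == 1
  observed[1, 2] <- observed[2, 1] <- TRUE
  partial <- partial_similarity(ids, values, observed)
  out <- integrate_similarity(kernel, partial)
  expect_equal(out["a", "b"], 0.7) # (0.8 + 0.6) / 2
  expect_equal(out["a", "c"], 0.3) # unobserved: kernel passthrough
  expect_equal(diag(out), c(a = 1, b = 1, c = 1))
  expect_silent(validate_similarity_matrix(out))

  bad <- partial_similarity(c("x", "y", "z"), values, observed)
  expect_error(integrate_similarity(kernel, bad), "identifiers")
})

test_that("kernel and integrated similarities satisfy matrix invariants", {
  set.seed(9)
  inst <- random_instance(6, 5, 11)
  profiles <- inst$A$values
  km <- gip_kernel(profiles, gip_bandwidth(profiles, 1))
  expect_silent(validate_similarity_matrix(km))
  expect_true(all(km > 0 & km <= 1))
})
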