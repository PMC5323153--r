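# Small in-code fixtures shared across test files.

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# random valid inputs for propagation tests: unit-diagonal symmetric
# similarity matrices and a binary association matrix with >= 1 edge
random_instance <- function(nm, nd, seed) {
  set.seed(seed)
  SM <- matrix(runif(nm * nm), nm, nm)
  SM <- (SM + t(SM)) / 2
  diag(SM) <- 1
  SD <- matrix(runif(nd * nd), nd, nd)
  SD <- (SD + t(SD)) / 2
  diag(SD) <- 1
  repeat {
    Av <- matrix(rbinom(nm * nd, 1, 0.3), nm, nd)
    if (sum(Av) >= 1) break
  }
  A <- association_matrix(Av, paste0("m", seq_len(nm)), paste0("d", seq_len(nd)))
  list(SM = SM, SD = SD, A = A,
       SMn = normalize_similarity(SM), SDn = normalize_similarity(SD))
}

# three-node sibling DAGs: grandparent G -> parent P -> each of D1, D2
sibling_mesh <- function() {
  read_mesh_tree_numbers(write_tsv_lines(c(
    "G\tC04",
    "P\tC04.100",
    "D1\tC04.100.200",
    "D2\tC04.100.300"
  )))
}

# a random chain-plus-branches MeSH table rooted at C01; returns the mesh
# mapping and the focal disease terms
random_mesh <- function(n_terms, seed) {
  set.seed(seed)
  nums <- "C01"
  while (length(nums) < n_terms) {
    parent <- sample(nums, 1)
    child <- paste(parent, sample(100:999, 1), sep = ".")
    if (!child %in% nums) nums <- c(nums, child)
  }
  terms <- paste0("t", seq_along(nums))
  mesh <- read_mesh_tree_numbers(write_tsv_lines(paste(terms, nums, sep = "\t")))
  list(mesh = mesh, terms = terms)
}
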