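# ---------------------------------------------------------------------------
# Optimal-assignment similarity: decay, recursive atom similarity, Hungarian
# assignment, normalization, and query-atom edge weights.
# ---------------------------------------------------------------------------

#' Topological decay factor of a neighbor atom
#'
#' The influence of a neighbor on an atom's environment similarity decreases
#' with its topological distance `dist` from the center as
#' `d = (1 - dist/3)^2`: 1 at the center, 4/9 at distance 1, 1/9 at distance 2,
#' and 0 just beyond the depth-2 neighborhood cutoff.
#'
#' @param mol an `oa_mol`.
#' @param center,nb 1-based atom indices with `topo_distance(mol, center, nb) <= 2`.
#' @return decay value in `[0, 1]`.
#' @export
decay <- function(mol, center, nb) {
  d <- topo_distance(mol, center, nb)
  if (!is.finite(d) || d > 2) stop("decay undefined beyond the depth-2 neighborhood")
  decay_value(d)
}

#' Decay as a function of topological distance
#' @param dist non-negative topological distance.
#' @return `(1 - dist/3)^2`.
#' @export
decay_value <- function(dist) (1 - dist / 3)^2

# resolve gamma defaults from a molecule's descriptor config
.gammas <- function(mol) {
  cfg <- mol$config
  ka <- ncol(mol$A)
  kb <- ncol(mol$Bdesc)
  list(ga = if (is.null(cfg$gamma_atom)) 1 / ka else cfg$gamma_atom,
       gab = if (is.null(cfg$gamma_env)) 1 / (ka + kb) else cfg$gamma_env,
       mix = cfg$mix, depth = cfg$depth)
}

#' Pairwise inter-molecule atom similarity matrix
#'
#' Entry `(i, j)` combines a radial-basis similarity of the standardized
#' descriptor vectors of atom `i` of `A` and atom `j` of `B` with a recursive
#' neighbor-environment term: the neighbors of the two atoms (atom descriptors
#' concatenated with the incident-bond descriptors) are matched by a small
#' optimal assignment of their pairwise similarities, damped by the topological
#' decay of their distance from the center, to the configured depth.  All
#' entries are in `[0, 1]`; `pairwise_matrix(A, A)` has a unit diagonal.
#'
#' @param A,B `oa_mol` molecules with descriptors computed.
#' @return an `n_atoms(A)` x `n_atoms(B)` numeric matrix.
#' @export
pairwise_matrix <- function(A, B) {
  stopifnot(inherits(A, "oa_mol"), inherits(B, "oa_mol"))
  if (A$n == 0L || B$n == 0L) stop("empty molecule")
  if (ncol(A$A) != ncol(B$A))
    stop("descriptor length mismatch between molecules")
  g <- .gammas(A)
  decays <- decay_value(seq_len(g$depth))
  cpp_sim_matrix(A$A, B$A, A$nbrs, B$nbrs, A$bdesc, B$bdesc,
                 g$ga, g$gab, g$mix, decays)
}

#' Similarity between two atoms of two molecules
#'
#' @param A,B `oa_mol` molecules with descriptors computed.
#' @param i,j 1-based atom indices into `A` and `B`.
#' @param depth neighbor recursion depth (default: the molecules' configured
#'   depth, 2).
#' @return similarity in `[0, 1]`, symmetric in `(A, i)` and `(B, j)`.
#' @export
atom_similarity <- function(A, i, B, j, depth = NULL) {
  stopifnot(inherits(A, "oa_mol"), inherits(B, "oa_mol"))
  if (ncol(A$A) != ncol(B$A))
    stop("descriptor length mismatch between molecules")
  g <- .gammas(A)
  if (is.null(depth)) depth <- g$depth
  decays <- if (depth > 0) decay_value(seq_len(depth)) else numeric(0)
  S <- cpp_sim_matrix(A$A, B$A, A$nbrs, B$nbrs, A$bdesc, B$bdesc,
                      g$ga, g$gab, g$mix, decays)
  S[i, j]
}

#' Solve the optimal assignment over an atom-similarity matrix
#'
#' Finds the injective mapping of the atoms of the smaller molecule onto a
#' subset of the atoms of the larger molecule that maximizes the sum of mapped
#' pairwise similarities (Hungarian method, `O(max(m, n)^3)`).
#'
#' @param S numeric matrix of pairwise similarities (finite).
#' @return a list of class `oa_assignment`: `score` (the maximum sum),
#'   `mapping` (for each atom of the smaller side, the matched index on the
#'   larger side), and `rows_are_smaller` (`TRUE` when the mapping indexes rows
#'   of `S` into columns).
#' @export
optimal_assignment <- function(S) {
  S <- as.matrix(S)
  if (!all(is.finite(S))) stop("similarity matrix must be finite")
  if (nrow(S) == 0L || ncol(S) == 0L) stop("empty similarity matrix")
  res <- cpp_lsap_max(S)
  structure(list(score = res$score, mapping = res$mapping,
                 rows_are_smaller = res$rows_are_smaller),
            class = "oa_assignment")
}

#' @export
print.oa_assignment <- function(x, ...) {
  cat("<oa_assignment> score ", format(x$score), ", ",
      length(x$mapping), " mapped atoms\n", sep = "")
  invisible(x)
}

#' Normalized optimal-assignment similarity of two molecules
#'
#' The raw assignment score is normalized to `[0, 1]` by the geometric mean of
#' the raw self-similarities, `S(A,B) / sqrt(S(A,A) * S(B,B))`.  Since every
#' diagonal self-similarity is 1, `S(A,A) = n_atoms(A)`.
#'
#' @param A,B `oa_mol` molecules.
#' @return similarity in `[0, 1]`; 1 for `A` against itself.
#' @export
normalized_similarity <- function(A, B) {
  S <- pairwise_matrix(A, B)
  oa <- optimal_assignment(S)
  oa$score / sqrt(A$n * B$n)
}

#' Map a bounded raw weight vector onto the constraint set
#'
#' Optimizers search raw vectors in `[-0.5, 0.5]^m`; the assignment requires
#' nonnegative weights summing to `m`.  The adopted mapping shifts by +0.5
#' (into `[0, 1]`) and rescales by `m / sum(shifted)`.  A degenerate all-zero
#' shifted vector maps to the uniform weights (all 1).  Entries outside the
#' bounds are clipped first.
#'
#' @param raw numeric vector of length `m >= 1`.
#' @return an `oa_weights` numeric vector: nonnegative, summing to `m`.
#' @export
normalize_weights <- function(raw) {
  m <- length(raw)
  if (m == 0L) stop("empty weight vector")
  shifted <- pmin(0.5, pmax(-0.5, raw)) + 0.5
  s <- sum(shifted)
  w <- if (s <= 0) rep(1, m) else shifted * (m / s)
  structure(w, class = "oa_weights")
}

#' Validate an assignment-edge weight vector
#' @param w numeric vector.
#' @param m expected length (query heavy-atom count).
#' @return the vector, invisibly, after checking nonnegativity and `sum == m`.
#' @export
check_weights <- function(w, m = length(w)) {
  if (length(w) != m) stop("weight/atom count mismatch")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (abs(sum(w) - m) > 1e-9) stop("weights must sum to the atom count")
  invisible(w)
}

#' Weighted optimal-assignment similarity of a query against a molecule
#'
#' Each assignment edge originating from query atom `i` is multiplied by the
#' edge weight `w_i`; the assignment maximizes the weighted sum.  Implemented
#' as the optimal assignment over the row-scaled matrix `diag(w) %*% S`.  The
#' normalized score divides by `sqrt(m * n)`, the geometric mean of the
#' identity-mapping weighted self-similarity of the query
#' (`sum(w_i * 1) = m`) and the raw self-similarity of `B`.
#'
#' @param Q query `oa_mol` with `m` heavy atoms.
#' @param B library `oa_mol`.
#' @param w an `oa_weights` vector of length `m` (see [normalize_weights()]).
#' @param S optional precomputed `pairwise_matrix(Q, B)`.
#' @return list of class `oa_assignment` with `score` (raw weighted score),
#'   `normalized` (in `[0, 1]`), and the mapping.
#' @export
weighted_similarity <- function(Q, B, w, S = NULL) {
  check_weights(w, Q$n)
  if (is.null(S)) S <- pairwise_matrix(Q, B)
  if (nrow(S) != Q$n) stop("similarity matrix does not match query")
  WS <- as.numeric(w) * S
  oa <- optimal_assignment(WS)
  oa$normalized <- oa$score / sqrt(Q$n * ncol(S))
  oa
}

#' Rank a screening library against a query
#'
#' Computes the (optionally weighted) normalized optimal-assignment similarity
#' of every library molecule to the query and returns a ranked list suitable
#' for the virtual-screening metrics.
#'
#' @param query `oa_mol` query molecule.
#' @param dataset an `oa_dataset` (or plain list of `oa_mol`).
#' @param weights optional `oa_weights` for the query (default: uniform,
#'   i.e. the unweighted similarity).
#' @param sim_matrices optional precomputed list of `pairwise_matrix(query, .)`
#'   per library molecule (see [precompute_sim_matrices()]).
#' @return for an `oa_dataset`, an [ranked_list()]; for a molecule list, a
#'   data.frame of id and score.
#' @export
oa_screen <- function(query, dataset, weights = NULL, sim_matrices = NULL) {
  mols <- if (inherits(dataset, "oa_dataset")) dataset$mols else dataset
  if (is.null(weights)) weights <- normalize_weights(rep(0, query$n))
  check_weights(weights, query$n)
  if (is.null(sim_matrices)) sim_matrices <- precompute_sim_matrices(query, mols)
  scores <- cpp_screen_scores(sim_matrices, as.numeric(weights))
  ids <- vapply(mols, function(m) m$id, "")
  if (inherits(dataset, "oa_dataset")) {
    ranked_list(ids, scores, dataset$info$label, dataset$info$cluster)
  } else {
    data.frame(id = ids, score = scores, stringsAsFactors = FALSE)
  }
}

#' Precompute query-vs-library similarity matrices
#'
#' The pairwise atom-similarity matrices do not depend on the edge weights, so
#' a screening run under many candidate weight vectors (as in weight
#' optimization) computes them once.
#'
#' @param query `oa_mol`.
#' @param mols list of `oa_mol`.
#' @return list of numeric matrices, one per library molecule.
#' @export
precompute_sim_matrices <- function(query, mols) {
  lapply(mols, function(m) pairwise_matrix(query, m))
}

# ---------------------------------------------------------------------------
# Weight file I/O (delimited text; header records query id and atom count)
# ---------------------------------------------------------------------------

#' Write query-atom edge weights to a delimited text file
#'
#' @param w `oa_weights` vector.
#' @param path output path.
#' @param query_id id recorded in the header.
#' @export
write_weights <- function(w, path, query_id = "query") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# query_id: ", query_id),
               paste0("# m: ", length(w)),
               "atom\tweight"), con)
  utils::write.table(data.frame(atom = seq_along(w) - 1L,
                                weight = as.numeric(w)),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read query-atom edge weights written by [write_weights()]
#'
#' @param path input path.
#' @return `oa_weights` vector with attributes `query_id` and `m`.
#' @export
read_weights <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  qid <- sub("^# query_id:\\s*", "", grep("^# query_id:", hdr, value = TRUE))
  body <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t")
  w <- structure(as.numeric(body[[2]]), class = "oa_weights")
  attr(w, "query_id") <- if (length(qid)) qid else NA_character_
  check_weights(w)
  w
}
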