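# ---------------------------------------------------------------------------
# Synthetic planted-pharmacophore datasets: actives carry a shared fragment
# (default: an indole attached to a carbonyl group) on cluster-specific
# scaffolds with random decorations; decoys reuse the same scaffolds and
# decorations plus confusable tails without the planted fragment.
# ---------------------------------------------------------------------------

.default_scaffolds <- c("c1ccccc1", "C1CCCCC1", "c1ccsc1", "C1CCNCC1",
                        "c1ccncc1", "C1CCOCC1", "c1ccc(C)cc1", "C1CCCC1")
.default_decorations <- c("C", "CC", "CCC", "CO", "CCO", "CN(C)C", "CC(C)",
                          "COC", "CCN")
# near-miss tails deliberately confusable with an indole-carbonyl:
# benzofuran-3-carbonyl (N -> O), benzothiophene-3-carbonyl (N -> S), indole
# without the carbonyl attachment, naphthoyl, plus easier aryl/acyl tails
.default_decoy_tails <- c("C(=O)c1coc2ccccc12", "C(=O)c1csc2ccccc12",
                          "c1c[nH]c2ccccc12", "C(=O)c1ccc2ccccc2c1",
                          "C(=O)c1ccco1", "C(=O)c1ccccc1",
                          "C(=O)N1CCCC1", "C(=O)OC")

#' Specification of a synthetic planted-pharmacophore dataset
#'
#' @param n_actives,n_decoys library composition (defaults 40 / 200).
#' @param n_clusters number of chemotype clusters among the actives
#'   (default 5, must be `<= n_actives`).
#' @param fragment planted substructure as an appendable SMILES suffix; the
#'   default is an indole attached to a carbonyl group.
#' @param scaffolds cluster scaffolds (appendable SMILES prefixes); the first
#'   `n_clusters` are used.
#' @param decorations decoration alphabet (SMILES prefixes).
#' @param decoy_tails suffix alphabet for decoys (no planted fragment).
#' @param label_noise fraction of actives whose label is swapped with a decoy
#'   (default 0).
#' @param seed integer seed.
#' @return a list of class `oa_fixture_spec`.
#' @export
fixture_spec <- function(n_actives = 40, n_decoys = 200, n_clusters = 5,
                         fragment = "C(=O)c1c[nH]c2ccccc12",
                         scaffolds = .default_scaffolds,
                         decorations = .default_decorations,
                         decoy_tails = .default_decoy_tails,
                         label_noise = 0, seed = 1L) {
  if (n_clusters > n_actives) stop("n_clusters must not exceed n_actives")
  if (n_clusters > length(scaffolds)) stop("not enough scaffolds for clusters")
  structure(list(n_actives = n_actives, n_decoys = n_decoys,
                 n_clusters = n_clusters, fragment = fragment,
                 scaffolds = scaffolds, decorations = decorations,
                 decoy_tails = decoy_tails, label_noise = label_noise,
                 seed = seed),
            class = "oa_fixture_spec")
}

#' Generate a synthetic planted-pharmacophore screening dataset
#'
#' Actives are built as `decoration + cluster scaffold + planted fragment`;
#' decoys reuse the same decoration and scaffold alphabets with confusable
#' tails (aryl ketones, amides, sulfones) but never contain the planted
#' fragment.  The query embeds the fragment in its own small scaffold (an
#' ethyl ketone), so only its fragment atoms discriminate actives from
#' decoys.  Deterministic from the seed in `spec`.
#'
#' @param spec an [fixture_spec()].
#' @return list with `dataset` (an `oa_dataset`), `query` (`oa_mol`),
#'   `query_smiles`, `fragment_atoms` (1-based indices of the planted-fragment
#'   atoms within the query), and `spec`.
#' @export
generate_planted_dataset <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "oa_fixture_spec"))
  frag_mol <- parse_smiles(sub("^C\\(=O\\)", "O=C", spec$fragment),
                           ids = "fragment")
  if (length(frag_mol) == 0) stop("planted fragment does not parse")
  set.seed(spec$seed)
  scaff <- spec$scaffolds[seq_len(spec$n_clusters)]
  cl_of <- rep(seq_len(spec$n_clusters), length.out = spec$n_actives)

  act_smiles <- vapply(seq_len(spec$n_actives), function(k) {
    deco <- sample(spec$decorations, 1)
    paste0(deco, scaff[cl_of[k]], spec$fragment)
  }, "")
  dec_smiles <- vapply(seq_len(spec$n_decoys), function(k) {
    deco <- sample(spec$decorations, 1)
    sc <- sample(spec$scaffolds, 1)
    tail <- sample(spec$decoy_tails, 1)
    paste0(deco, sc, tail)
  }, "")

  smiles <- c(act_smiles, dec_smiles)
  ids <- c(sprintf("a%03d", seq_len(spec$n_actives)),
           sprintf("d%03d", seq_len(spec$n_decoys)))
  label <- c(rep("active", spec$n_actives), rep("decoy", spec$n_decoys))
  cluster <- c(sprintf("cl%d", cl_of), rep(NA_character_, spec$n_decoys))

  if (spec$label_noise > 0) {
    k <- round(spec$label_noise * spec$n_actives)
    if (k > 0) {
      fa <- sample(which(label == "active"), k)
      fd <- sample(which(label == "decoy"), k)
      label[fa] <- "decoy"
      label[fd] <- "active"
      cluster[fd] <- sample(sprintf("cl%d", seq_len(spec$n_clusters)), k,
                            replace = TRUE)
      cluster[fa] <- NA_character_
    }
  }

  mols <- parse_smiles(smiles, ids)
  errs <- attr(mols, "errors")
  if (nrow(errs) > 0)
    stop("fixture SMILES failed to parse: ",
         paste(errs$id, collapse = ", "))
  dataset <- oa_dataset(mols, label, cluster)

  query_smiles <- paste0("CC", spec$fragment)
  query <- parse_smiles(query_smiles, ids = "query")[[1]]
  frag_atoms <- substructure_match(frag_mol[[1]], query, mapping = TRUE)
  list(dataset = dataset, query = query, query_smiles = query_smiles,
       fragment_atoms = frag_atoms, spec = spec)
}

#' Heavy-atom substructure match
#'
#' Non-induced subgraph isomorphism of the pattern's heavy-atom skeleton into
#' the target (LAD algorithm) with element-compatibility domains; bond orders
#' are not compared.
#'
#' @param pattern,target `oa_mol` molecules.
#' @param mapping if `TRUE`, return the matched target atom indices of one
#'   embedding (or `NULL`); otherwise a logical.
#' @return logical, or an integer vector of target atom indices.
#' @export
substructure_match <- function(pattern, target, mapping = FALSE) {
  stopifnot(inherits(pattern, "oa_mol"), inherits(target, "oa_mol"))
  if (pattern$n > target$n || nrow(pattern$bonds) > nrow(target$bonds))
    return(if (mapping) NULL else FALSE)
  gp <- igraph::make_empty_graph(pattern$n, directed = FALSE)
  if (nrow(pattern$bonds) > 0)
    gp <- igraph::add_edges(gp, rbind(pattern$bonds$i, pattern$bonds$j))
  gt <- igraph::make_empty_graph(target$n, directed = FALSE)
  if (nrow(target$bonds) > 0)
    gt <- igraph::add_edges(gt, rbind(target$bonds$i, target$bonds$j))
  domains <- lapply(seq_len(pattern$n), function(a) {
    which(target$elements == pattern$elements[a])
  })
  if (any(vapply(domains, length, 1L) == 0))
    return(if (mapping) NULL else FALSE)
  res <- igraph::subgraph_isomorphisms(pattern = gp, target = gt,
                                       method = "lad", induced = FALSE,
                                       domains = domains)
  if (length(res) == 0) return(if (mapping) NULL else FALSE)
  if (mapping) as.integer(res[[1]]) else TRUE
}

#' Write a screening-dataset manifest
#'
#' Delimited text with columns `id`, `smiles`, `label`, `cluster` (empty for
#' unclustered records); round-trips through [read_manifest()].
#'
#' @param dataset an `oa_dataset` whose molecules carry SMILES.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_manifest <- function(dataset, path, sep = "\t") {
  stopifnot(inherits(dataset, "oa_dataset"))
  smi <- vapply(dataset$mols, function(m) m$smiles, "")
  if (any(is.na(smi))) stop("dataset molecules carry no SMILES")
  d <- data.frame(id = dataset$info$id, smiles = smi,
                  label = dataset$info$label,
                  cluster = ifelse(is.na(dataset$info$cluster), "",
                                   dataset$info$cluster),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a screening-dataset manifest
#'
#' @param path manifest path (columns `id`, `smiles`, `label`, optional
#'   `cluster`).
#' @param sep field separator (default tab).
#' @param config descriptor configuration for parsing.
#' @return an `oa_dataset`.
#' @export
read_manifest <- function(path, sep = "\t",
                          config = default_descriptor_config()) {
  d <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  if (!all(c("id", "smiles", "label") %in% names(d)))
    stop("manifest must have id, smiles and label columns")
  mols <- parse_smiles(d$smiles, as.character(d$id), config)
  errs <- attr(mols, "errors")
  keep <- setdiff(seq_len(nrow(d)), errs$index)
  if (nrow(errs) > 0)
    warning(nrow(errs), " manifest record(s) failed to parse")
  cl <- if ("cluster" %in% names(d)) as.character(d$cluster)[keep] else NULL
  oa_dataset(mols, d$label[keep], cl)
}

#' Write fixture files (.smi library, manifest, query)
#'
#' Emits the screening library as a SMILES file, the dataset manifest, and
#' the query as a one-line SMILES file.
#'
#' @param fx result of [generate_planted_dataset()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the written paths.
#' @export
write_fixture <- function(fx, dir, prefix = "fixture") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  smi_path <- file.path(dir, paste0(prefix, ".smi"))
  man_path <- file.path(dir, paste0(prefix, "_manifest.tsv"))
  query_path <- file.path(dir, paste0(prefix, "_query.smi"))
  smi <- vapply(fx$dataset$mols, function(m) m$smiles, "")
  writeLines(paste(smi, fx$dataset$info$id), smi_path)
  write_manifest(fx$dataset, man_path)
  writeLines(paste(fx$query_smiles, "query"), query_path)
  invisible(c(smi = smi_path, manifest = man_path, query = query_path))
}
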