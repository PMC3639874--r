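#' @useDynLib oascreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif median sd setNames
#' @importFrom utils read.delim write.table head
NULL

# Pauling electronegativities and atomic masses for the elements the package
# expects to see in drug-like molecules.  Unknown elements fall back to a
# neutral value with a warning (the descriptor error contract).
.EN <- c(H = 2.20, Li = 0.98, Be = 1.57, B = 2.04, C = 2.55, N = 3.04,
         O = 3.44, F = 3.98, Na = 0.93, Mg = 1.31, Si = 1.90, P = 2.19,
         S = 2.58, Cl = 3.16, K = 0.82, Ca = 1.00, Fe = 1.83, Cu = 1.90,
         Zn = 1.65, Se = 2.55, Br = 2.96, I = 2.66)
.MASS <- c(H = 1.008, Li = 6.94, Be = 9.012, B = 10.81, C = 12.011,
           N = 14.007, O = 15.999, F = 18.998, Na = 22.990, Mg = 24.305,
           Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
           Ca = 40.078, Fe = 55.845, Cu = 63.546, Zn = 65.38, Se = 78.971,
           Br = 79.904, I = 126.904)

#' Default atom/bond descriptor configuration
#'
#' Defines the per-atom and per-bond physico-chemical descriptors used by the
#' radial-basis atom similarity, together with the fixed affine standardization
#' range of each descriptor.  Ranges are constants of the configuration (not
#' data-dependent), so similarity values are stable across screening libraries.
#'
#' Atom descriptors (k_a = 10): Pauling electronegativity, atomic mass,
#' heavy-atom degree, total hydrogen count, formal charge, aromaticity flag,
#' ring-membership flag, hybridization code (1 = sp, 2 = sp2, 3 = sp3),
#' estimated partial charge (one-pass electronegativity-difference model),
#' conjugation flag.  Bond descriptors (k_b = 4): bond order (aromatic = 1.5),
#' aromaticity flag, ring flag, conjugation flag.
#'
#' @param gamma_atom RBF width for the center-atom term.  The default 8
#'   corresponds to a Gaussian bandwidth of 0.25 on the standardized
#'   `[0, 1]` descriptor scale (`gamma = 1 / (2 * 0.25^2)`), sharp enough to
#'   distinguish heteroatom substitutions (N vs O) that a width of the full
#'   descriptor range would wash out.
#' @param gamma_env RBF width for the neighbor (atom + bond) term (same
#'   default and rationale).
#' @param mix mixing weight of the neighbor-environment term in `[0, 1]`.
#' @param depth neighbor recursion depth (topological distance considered).
#' @return a list with elements `atom`, `bond` (named lists of `c(lo, hi)`
#'   standardization ranges), `gamma_atom`, `gamma_env`, `mix`, `depth`.
#' @export
default_descriptor_config <- function(gamma_atom = 8, gamma_env = 8,
                                      mix = 0.5, depth = 2) {
  list(
    atom = list(en = c(0.7, 4.0), mass = c(1, 130), degree = c(0, 6),
                hcount = c(0, 4), charge = c(-2, 2), aromatic = c(0, 1),
                ring = c(0, 1), hybrid = c(0, 3), pcharge = c(-1, 1),
                conj = c(0, 1)),
    bond = list(order = c(0, 3), aromatic = c(0, 1), ring = c(0, 1),
                conj = c(0, 1)),
    gamma_atom = gamma_atom, gamma_env = gamma_env, mix = mix, depth = depth
  )
}

#' Read a descriptor configuration from YAML or JSON
#'
#' The file may override any subset of the default configuration; omitted
#' entries keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a descriptor configuration list (see [default_descriptor_config()]).
#' @export
read_descriptor_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_descriptor_config()
  for (nm in intersect(names(raw), c("gamma_atom", "gamma_env", "mix", "depth")))
    cfg[[nm]] <- raw[[nm]]
  for (blk in c("atom", "bond")) {
    if (!is.null(raw[[blk]])) {
      cfg[[blk]] <- lapply(raw[[blk]], function(r) as.numeric(unlist(r)))
    }
  }
  cfg
}

# ---------------------------------------------------------------------------
# Molecule graph construction
# ---------------------------------------------------------------------------

# Build the molecular graph skeleton (elements, charges, bonds, ring and
# aromaticity perception, implicit hydrogens) from a ChemmineR SDF object.
# OpenBabel emits kekulized SDF, so aromaticity is re-perceived with a
# simplified Hueckel rule documented in the methods vignette.
.mol_skeleton <- function(sdf, id) {
  ab <- ChemmineR::atomblock(sdf)
  n <- nrow(ab)
  if (n == 0L) stop("empty molecule: ", id)
  elements <- sub("_.*$", "", rownames(ab))
  binfo <- ChemmineR::bonds(sdf, type = "bonds")
  charge <- as.numeric(binfo$charge)
  valence <- as.numeric(binfo$Nbondrule)

  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) %/% 7, ncol = 7,
                                     byrow = FALSE)
  nb <- nrow(bb)
  bi <- if (nb > 0) as.integer(bb[, 1]) else integer(0)
  bj <- if (nb > 0) as.integer(bb[, 2]) else integer(0)
  border <- if (nb > 0) as.numeric(bb[, 3]) else numeric(0)
  arom_bond <- border == 4          # explicit aromatic order in input SDF
  border[arom_bond] <- 1.5

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nb > 0) g <- igraph::add_edges(g, rbind(bi, bj))

  # ring perception: ring bonds are the non-bridge edges
  ring_bond <- rep(FALSE, nb)
  if (nb > 0) {
    br <- igraph::bridges(g)
    ring_bond <- !(seq_len(nb) %in% as.integer(br))
  }
  ring_atom <- rep(FALSE, n)
  if (any(ring_bond)) ring_atom[unique(c(bi[ring_bond], bj[ring_bond]))] <- TRUE

  # bond-order bookkeeping per atom
  ordsum <- rep(0, n); ndouble <- rep(0L, n); hasmult <- rep(FALSE, n)
  for (e in seq_len(nb)) {
    for (a in c(bi[e], bj[e])) {
      ordsum[a] <- ordsum[a] + border[e]
      if (border[e] >= 2) ndouble[a] <- ndouble[a] + 1L
      if (border[e] > 1) hasmult[a] <- TRUE
    }
  }

  # simplified Hueckel aromaticity on the kekulized graph: a 5- or 6-ring is
  # aromatic when every member is either incident to a multiple bond (1 pi
  # electron) or an N/O/S donating a lone pair (2 pi electrons) and the pi
  # count is 6
  aromatic <- rep(FALSE, n)
  if (any(arom_bond)) aromatic[unique(c(bi[arom_bond], bj[arom_bond]))] <- TRUE
  if (any(ring_bond)) {
    rings <- .find_rings(g, bi, bj, ring_bond, max_size = 6L)
    for (r in rings) {
      pi_e <- 0L; ok <- TRUE
      for (a in r) {
        if (hasmult[a]) pi_e <- pi_e + 1L
        else if (elements[a] %in% c("N", "O", "S")) pi_e <- pi_e + 2L
        else { ok <- FALSE; break }
      }
      if (ok && pi_e == 6L) {
        aromatic[r] <- TRUE
        for (e in which(ring_bond)) {
          if (bi[e] %in% r && bj[e] %in% r) arom_bond[e] <- TRUE
        }
      }
    }
  }

  has_triple <- vapply(seq_len(n), function(a)
    any(border[bi == a | bj == a] >= 3), TRUE)
  hyb <- ifelse(has_triple | ndouble >= 2L, 1L,
                ifelse(hasmult | aromatic, 2L, 3L))

  # implicit hydrogens from the standard-valence rule, charge-adjusted
  charge_adj <- ifelse(elements %in% c("N", "P", "O", "S"), charge,
                       -abs(charge))
  hcount <- pmax(0, round(valence + charge_adj - ordsum))

  degree <- igraph::degree(g)
  conj_atom <- hyb <= 2L
  conj_atom <- conj_atom &
    vapply(seq_len(n), function(a) {
      nbrs <- unique(c(bj[bi == a], bi[bj == a]))
      length(nbrs) > 0 && any(hyb[nbrs] <= 2L)
    }, TRUE)
  conj_atom <- conj_atom | aromatic
  conj_bond <- if (nb > 0) conj_atom[bi] & conj_atom[bj] else logical(0)
  arom_bond2 <- arom_bond | (if (nb > 0) aromatic[bi] & aromatic[bj] & ring_bond else logical(0))
  border[arom_bond2] <- 1.5  # descriptor order of perceived aromatic bonds

  dist <- igraph::distances(g)

  list(id = id, n = n, elements = elements, charge = charge,
       hcount = hcount, degree = degree, aromatic = aromatic,
       ring_atom = ring_atom, hybrid = hyb, conj = conj_atom,
       bonds = data.frame(i = bi, j = bj, order = border,
                          aromatic = arom_bond2, ring = ring_bond,
                          conj = conj_bond),
       dist = dist)
}

# minimal skeleton for a bond-less (single heavy atom) molecule, which the
# SDF container class cannot represent
.single_atom_skeleton <- function(element, charge, id) {
  val <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
           I = 1, B = 3, Si = 4)
  v <- if (element %in% names(val)) unname(val[element]) else 0
  adj <- if (element %in% c("N", "P", "O", "S")) charge else -abs(charge)
  list(id = id, n = 1L, elements = element, charge = charge,
       hcount = max(0, v + adj), degree = 0L, aromatic = FALSE,
       ring_atom = FALSE, hybrid = 3L, conj = FALSE,
       bonds = data.frame(i = integer(0), j = integer(0), order = numeric(0),
                          aromatic = logical(0), ring = logical(0),
                          conj = logical(0)),
       dist = matrix(0, 1, 1))
}

# ---------------------------------------------------------------------------
# SDF record plumbing (text level)
# ---------------------------------------------------------------------------

# split SDF text lines into records (terminator lines dropped)
.split_sdf_records <- function(lines) {
  ends <- grep("^\\${4}", lines)
  if (length(ends) == 0) return(list())
  starts <- c(1L, head(ends, -1) + 1L)
  recs <- Map(function(a, b) lines[a:(b - 1L)], starts, ends)
  recs[vapply(recs, function(r) any(nzchar(trimws(r))), TRUE)]
}

.record_counts <- function(rec) {
  cl <- rec[4]
  c(atoms = as.integer(substr(cl, 1, 3)), bonds = as.integer(substr(cl, 4, 6)))
}

.record_field <- function(rec, name) {
  hit <- grep(paste0("^>.*<", name, ">"), rec)
  if (length(hit) == 0 || hit[1] + 1 > length(rec)) return(NA_character_)
  rec[hit[1] + 1]
}

# build an oa_mol from one SDF record (text lines); sdf may carry the already
# parsed ChemmineR object for the record to avoid re-reading
.mol_from_record <- function(rec, id, config, sdf = NULL,
                             smiles = NA_character_) {
  cnt <- .record_counts(rec)
  if (is.na(cnt["atoms"]) || cnt["atoms"] < 1L)
    stop("record has no atoms: ", id)
  if (cnt["bonds"] == 0L) {
    if (cnt["atoms"] > 1L)
      stop("multi-fragment record without bonds unsupported: ", id)
    atomline <- rec[5]
    element <- trimws(substr(atomline, 32, 34))
    charge <- 0
    chg <- grep("^M  CHG", rec, value = TRUE)
    if (length(chg) > 0) charge <- as.numeric(strsplit(trimws(chg[1]),
                                                       "\\s+")[[1]][5])
    mol <- .single_atom_skeleton(element, charge, id)
  } else {
    if (is.null(sdf)) {
      sdfset <- suppressWarnings(ChemmineR::read.SDFset(c(rec, "$$$$")))
      sdf <- sdfset[[1]]
    }
    mol <- .mol_skeleton(sdf, id)
  }
  mol$molblock <- rec
  mol$smiles <- smiles
  class(mol) <- "oa_mol"
  compute_descriptors(mol, config)
}

# Small rings (size <= max_size) through each ring edge: remove the edge and
# take a shortest path between its endpoints.  Returns a list of unique atom
# index vectors.
.find_rings <- function(g, bi, bj, ring_bond, max_size = 6L) {
  rings <- list()
  seen <- character(0)
  for (e in which(ring_bond)) {
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = bi[e], to = bj[e]))
    p <- as.integer(sp$vpath[[1]])
    if (length(p) >= 3 && length(p) <= max_size) {
      key <- paste(sort(p), collapse = ",")
      if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- p }
    }
  }
  rings
}

#' Compute standardized atom and bond descriptor vectors
#'
#' Populates the per-atom and per-bond descriptor matrices of a molecule graph
#' using the descriptor set and fixed affine standardization ranges of
#' `config`.  Standardized values are clipped to `[0, 1]`; a descriptor that
#' cannot be computed for an atom (e.g. an element missing from the property
#' tables) is imputed at the neutral value 0.5 with a warning.
#'
#' @param mol an `oa_mol` molecule graph.
#' @param config a descriptor configuration (see [default_descriptor_config()]).
#' @return the molecule with descriptor matrices populated (fields `A`,
#'   `bdesc`, `nbrs`, `config`).
#' @export
compute_descriptors <- function(mol, config = default_descriptor_config()) {
  stopifnot(inherits(mol, "oa_mol"))
  n <- mol$n
  unknown <- setdiff(unique(mol$elements), names(.EN))
  if (length(unknown) > 0)
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            " in ", mol$id, "; descriptor values imputed as neutral")
  en <- unname(.EN[mol$elements])
  mass <- unname(.MASS[mol$elements])

  # one-pass electronegativity-difference partial charge estimate
  pch <- mol$charge
  for (e in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[e]; j <- mol$bonds$j[e]; o <- mol$bonds$order[e]
    if (is.na(en[i]) || is.na(en[j])) next
    d <- 0.1 * o * (en[j] - en[i])
    pch[i] <- pch[i] + d
    pch[j] <- pch[j] - d
  }

  raw_atom <- list(en = en, mass = mass, degree = mol$degree,
                   hcount = mol$hcount, charge = mol$charge,
                   aromatic = as.numeric(mol$aromatic),
                   ring = as.numeric(mol$ring_atom),
                   hybrid = as.numeric(mol$hybrid), pcharge = pch,
                   conj = as.numeric(mol$conj))
  anames <- names(config$atom)
  A <- matrix(NA_real_, n, length(anames), dimnames = list(NULL, anames))
  for (k in seq_along(anames)) {
    nm <- anames[k]
    v <- raw_atom[[nm]]
    if (is.null(v)) stop("unknown atom descriptor in config: ", nm)
    r <- config$atom[[nm]]
    A[, k] <- pmin(1, pmax(0, (v - r[1]) / (r[2] - r[1])))
  }
  A[!is.finite(A)] <- 0.5

  bnames <- names(config$bond)
  raw_bond <- list(order = mol$bonds$order,
                   aromatic = as.numeric(mol$bonds$aromatic),
                   ring = as.numeric(mol$bonds$ring),
                   conj = as.numeric(mol$bonds$conj))
  B <- matrix(NA_real_, nrow(mol$bonds), length(bnames),
              dimnames = list(NULL, bnames))
  for (k in seq_along(bnames)) {
    nm <- bnames[k]
    v <- raw_bond[[nm]]
    if (is.null(v)) stop("unknown bond descriptor in config: ", nm)
    r <- config$bond[[nm]]
    B[, k] <- pmin(1, pmax(0, (v - r[1]) / (r[2] - r[1])))
  }
  B[!is.finite(B)] <- 0.5

  # neighbor lists and per-atom incident-bond descriptor rows
  nbrs <- vector("list", n)
  bdesc <- vector("list", n)
  for (a in seq_len(n)) {
    idx <- which(mol$bonds$i == a | mol$bonds$j == a)
    other <- ifelse(mol$bonds$i[idx] == a, mol$bonds$j[idx], mol$bonds$i[idx])
    nbrs[[a]] <- as.integer(other)
    bdesc[[a]] <- B[idx, , drop = FALSE]
  }

  mol$A <- A
  mol$Bdesc <- B
  mol$nbrs <- nbrs
  mol$bdesc <- bdesc
  mol$config <- config
  mol
}

#' Parse SMILES strings into molecule graphs
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional ids (defaults to element index).
#' @param config descriptor configuration.
#' @return list of `oa_mol` objects; unparsable entries are dropped and
#'   reported in the `"errors"` attribute (a data.frame of index/id/message).
#' @export
parse_smiles <- function(smiles, ids = NULL, config = default_descriptor_config()) {
  if (is.null(ids)) ids <- as.character(seq_along(smiles))
  mols <- list()
  errs <- data.frame(index = integer(0), id = character(0),
                     message = character(0), stringsAsFactors = FALSE)
  for (k in seq_along(smiles)) {
    res <- tryCatch({
      txt <- ChemmineOB::convertFormat("SMI", "SDF",
                                       paste(smiles[k], ids[k]))
      if (!nzchar(txt)) stop("SMILES failed to parse")
      rec <- .split_sdf_records(strsplit(txt, "\n", fixed = TRUE)[[1]])
      if (length(rec) == 0) stop("SMILES failed to parse")
      .mol_from_record(rec[[1]], ids[k], config, smiles = smiles[k])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs <- rbind(errs, data.frame(index = k, id = ids[k],
                                     message = conditionMessage(res),
                                     stringsAsFactors = FALSE))
    } else {
      mols[[length(mols) + 1L]] <- res
    }
  }
  attr(mols, "errors") <- errs
  mols
}

#' Read molecules from a SMILES file
#'
#' One molecule per line; an optional second whitespace-separated token is
#' taken as the molecule id (default: line number).  Unparsable lines are
#' collected in the `"errors"` attribute and the run continues.
#'
#' @param path path to a `.smi` file.
#' @param config descriptor configuration.
#' @return list of `oa_mol` (empty for an empty file), with `"errors"` attribute.
#' @export
read_smiles <- function(path, config = default_descriptor_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- list()
    attr(out, "errors") <- data.frame(index = integer(0), id = character(0),
                                      message = character(0))
    return(out)
  }
  toks <- strsplit(trimws(lines), "\\s+")
  smi <- vapply(toks, `[[`, "", 1L)
  ids <- vapply(seq_along(toks), function(k) {
    if (length(toks[[k]]) >= 2) toks[[k]][[2]] else as.character(k)
  }, "")
  parse_smiles(smi, ids, config)
}

#' Read molecules from an SDF file
#'
#' @param path path to a V2000/V3000 SDF file.
#' @param id_field optional SDF data field to use as id; default is the
#'   molfile title line (falling back to record number).
#' @param config descriptor configuration.
#' @return list of `oa_mol` with an `"errors"` attribute for malformed records.
#' @export
read_sdf <- function(path, id_field = NULL, config = default_descriptor_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- .split_sdf_records(lines)
  mols <- list()
  errs <- data.frame(index = integer(0), id = character(0),
                     message = character(0), stringsAsFactors = FALSE)
  if (length(recs) == 0L) {
    attr(mols, "errors") <- errs
    return(mols)
  }
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                     error = function(e) NULL)
  for (k in seq_along(recs)) {
    res <- tryCatch({
      rec <- recs[[k]]
      id <- if (!is.null(id_field)) .record_field(rec, id_field) else NA
      if (is.na(id) || !nzchar(trimws(id))) id <- trimws(rec[1])
      if (!nzchar(id)) id <- as.character(k)
      sdf <- if (!is.null(sdfset) && k <= length(sdfset)) sdfset[[k]] else NULL
      .mol_from_record(rec, id, config, sdf = sdf)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs <- rbind(errs, data.frame(index = k, id = as.character(k),
                                     message = conditionMessage(res),
                                     stringsAsFactors = FALSE))
    } else {
      mols[[length(mols) + 1L]] <- res
    }
  }
  attr(mols, "errors") <- errs
  mols
}

#' Topological distance between two atoms
#'
#' Length of the shortest bond path; 0 iff `i == j`; `Inf` for atoms in
#' different fragments.
#'
#' @param mol an `oa_mol`.
#' @param i,j 1-based atom indices.
#' @return non-negative integer (or `Inf`).
#' @export
topo_distance <- function(mol, i, j) {
  stopifnot(inherits(mol, "oa_mol"))
  if (i < 1 || i > mol$n || j < 1 || j > mol$n) stop("atom index out of range")
  mol$dist[i, j]
}

#' Number of heavy atoms in a molecule graph
#' @param mol an `oa_mol`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) {
  stopifnot(inherits(mol, "oa_mol"))
  mol$n
}

#' @export
print.oa_mol <- function(x, ...) {
  cat("<oa_mol> ", x$id, ": ", x$n, " heavy atoms, ",
      nrow(x$bonds), " bonds", sep = "")
  if (!is.na(x$smiles)) cat("  [", x$smiles, "]", sep = "")
  cat("\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Screening dataset container
# ---------------------------------------------------------------------------

#' Construct a screening dataset
#'
#' Bundles library molecules with their activity labels and optional chemotype
#' cluster ids.  Ids must be unique; every active in a dataset that carries
#' cluster annotations must have a cluster (decoys need none).
#'
#' @param mols list of `oa_mol`.
#' @param label character vector, `"active"` or `"decoy"`, one per molecule.
#' @param cluster optional character vector of chemotype cluster ids (`NA`
#'   allowed for decoys).
#' @return an object of class `oa_dataset` with fields `mols` and `info`
#'   (data.frame id/label/cluster).
#' @export
oa_dataset <- function(mols, label, cluster = NULL) {
  stopifnot(length(mols) == length(label))
  label <- match.arg(label, c("active", "decoy"), several.ok = TRUE)
  ids <- vapply(mols, function(m) m$id, "")
  if (anyDuplicated(ids)) stop("duplicate molecule ids in dataset")
  if (is.null(cluster)) cluster <- rep(NA_character_, length(mols))
  if (any(!is.na(cluster))) {
    miss <- label == "active" & is.na(cluster)
    if (any(miss))
      stop("actives without cluster in a cluster-annotated dataset: ",
           paste(ids[miss], collapse = ", "))
  }
  structure(list(mols = mols,
                 info = data.frame(id = ids, label = label,
                                   cluster = as.character(cluster),
                                   stringsAsFactors = FALSE)),
            class = "oa_dataset")
}

#' @export
print.oa_dataset <- function(x, ...) {
  tab <- table(x$info$label)
  ncl <- length(unique(stats::na.omit(x$info$cluster)))
  cat("<oa_dataset> ", nrow(x$info), " molecules (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")",
      if (ncl > 0) paste0(", ", ncl, " chemotype clusters"), "\n", sep = "")
  invisible(x)
}

#' @export
length.oa_dataset <- function(x) nrow(x$info)
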