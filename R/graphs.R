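# Atomistic graphs: the protein graph G_p over cBS-union-cAS residues
# (CA nodes plus one key functional sidechain atom per residue, kNN edges,
# k = 64) and the ligand graph G_l (heavy atoms, covalent edges, one 3D
# conformer). Protein nodes carry a 34-dimensional learned feature vector
# plus the 3 coordinates on the equivariant channel (37 descriptors per
# node); ligand nodes carry 19 features plus coordinates.

# One key functional sidechain atom per residue type; aliphatic residues
# contribute only their CA node.
.SIDECHAIN_ATOM <- c(ARG = "CZ", LYS = "NZ", HIS = "NE2", ASP = "OD1",
                     GLU = "OE1", ASN = "OD1", GLN = "OE1", SER = "OG",
                     THR = "OG1", TYR = "OH", TRP = "NE1", CYS = "SG",
                     MET = "SD", PHE = "CZ")

.AA20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")

# Physicochemical residue descriptors (9): Kyte-Doolittle hydropathy
# normalized to [-1, 1]; net sidechain charge at pH 7 (His partial);
# polar flag; aromatic flag; sidechain volume normalized by Trp; H-bond
# donor count; H-bond acceptor count; sulfur flag; normalized flexibility
# index (B-factor-derived scale).
.AA_PROPS <- local({
  kd <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
          GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
          LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
          SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2)
  charge <- c(ARG = 1, LYS = 1, HIS = 0.1, ASP = -1, GLU = -1)
  polar <- c("ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "HIS", "LYS",
             "SER", "THR", "TYR", "TRP")
  arom <- c("PHE", "TYR", "TRP", "HIS")
  vol <- c(ALA = 88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1, CYS = 108.5,
           GLN = 143.8, GLU = 138.4, GLY = 60.1, HIS = 153.2, ILE = 166.7,
           LEU = 166.7, LYS = 168.6, MET = 162.9, PHE = 189.9, PRO = 112.7,
           SER = 89.0, THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0)
  don <- c(ARG = 3, ASN = 1, GLN = 1, HIS = 1, LYS = 1, SER = 1, THR = 1,
           TRP = 1, TYR = 1, CYS = 1)
  acc <- c(ASN = 1, ASP = 2, GLN = 1, GLU = 2, HIS = 1, SER = 1, THR = 1,
           TYR = 1, MET = 1)
  flex <- c(ALA = 0.36, ARG = 0.53, ASN = 0.46, ASP = 0.51, CYS = 0.35,
            GLN = 0.49, GLU = 0.50, GLY = 0.54, HIS = 0.32, ILE = 0.46,
            LEU = 0.37, LYS = 0.47, MET = 0.30, PHE = 0.31, PRO = 0.51,
            SER = 0.51, THR = 0.44, TRP = 0.31, TYR = 0.42, VAL = 0.39)
  m <- matrix(0, length(.AA20), 9,
              dimnames = list(.AA20,
                              c("hydropathy", "charge", "polar", "aromatic",
                                "volume", "donors", "acceptors", "sulfur",
                                "flexibility")))
  m[, "hydropathy"] <- kd[.AA20] / 4.5
  m[names(charge), "charge"] <- charge
  m[polar, "polar"] <- 1
  m[arom, "aromatic"] <- 1
  m[, "volume"] <- vol[.AA20] / max(vol)
  m[names(don), "donors"] <- don
  m[names(acc), "acceptors"] <- acc
  m[c("CYS", "MET"), "sulfur"] <- 1
  m[, "flexibility"] <- flex[.AA20]
  m
})

#' Feature layout of protein and ligand graph nodes
#'
#' Returns named slices of the learned feature vectors: the protein
#' 34-vector (residue one-hot + unknown, cBS/cAS flags, CA/sidechain role
#' flags, 9 physicochemical descriptors; the 3 coordinates ride on the
#' equivariant channel for 37 descriptors per node) and the ligand
#' 19-vector (element one-hot over C,N,O,S,P,F,Cl,Br,I,other;
#' hybridization sp/sp2/sp3; aromatic, ring; formal charge; attached-H
#' count; donor and acceptor flags).
#' @return List with `protein` and `ligand` slice index lists.
#' @export
feature_layout <- function() {
  list(protein = list(residue_onehot = 1:20, residue_unknown = 21L,
                      cbs_flag = 22L, cas_flag = 23L, role_ca = 24L,
                      role_sidechain = 25L, physchem = 26:34),
       ligand = list(element_onehot = 1:10, hybridization = 11:13,
                     aromatic = 14L, ring = 15L, formal_charge = 16L,
                     attached_h = 17L, donor = 18L, acceptor = 19L))
}

#' Select protein graph nodes for site residues
#'
#' For every residue in `union(cbs, cas)` (structure order): its CA node,
#' plus one key functional sidechain atom per the fixed residue table.
#' Aliphatic residues (Gly, Ala, Val, Leu, Ile, Pro) contribute CA only;
#' a listed sidechain atom missing from the file is skipped with a
#' warning.
#'
#' @param structure A `gpcr_structure`.
#' @param sites List with `cbs` and `cas` residue-key vectors.
#' @param sidechain_table Named map residue -> atom name (configurable).
#' @return Data frame: `residue_key`, `atom_name`, `role` (`"CA"` /
#'   `"sidechain"`), `resid`.
#' @export
select_protein_nodes <- function(structure, sites,
                                 sidechain_table = .SIDECHAIN_ATOM) {
  res <- union(sites$cbs, sites$cas)
  if (!length(res)) stop("empty protein graph: no site residues")
  res <- res[order(match(res, residue_keys(structure)))]
  at <- structure$atom
  akey <- .atom_res_key(at)
  rows <- vector("list", length(res))
  for (i in seq_along(res)) {
    k <- res[i]
    sub <- at[akey == k, , drop = FALSE]
    if (!nrow(sub)) stop("site residue absent from structure: ", k)
    if (!("CA" %in% sub$elety)) stop("residue without CA atom: ", k)
    resid <- sub$resid[1L]
    out <- data.frame(residue_key = k, atom_name = "CA", role = "CA",
                      resid = resid, stringsAsFactors = FALSE)
    sc <- sidechain_table[resid]
    if (!is.na(sc)) {
      if (sc %in% sub$elety) {
        out <- rbind(out, data.frame(residue_key = k, atom_name = sc,
                                     role = "sidechain", resid = resid,
                                     stringsAsFactors = FALSE))
      } else {
        warning("missing sidechain atom ", sc, " for ", resid, " ", k,
                "; node skipped")
      }
    }
    rows[[i]] <- out
  }
  do.call(rbind, rows)
}

# Directed kNN edge list: each node i gets edges i -> j for its k_eff
# nearest neighbours; distance ties broken by node index.
.knn_edges <- function(coords, k) {
  n <- nrow(coords)
  k_eff <- min(k, n - 1L)
  d2 <- round(as.matrix(stats::dist(coords))^2, 6L)  # tie-stable
  diag(d2) <- Inf
  src <- rep(seq_len(n), each = k_eff)
  dst <- integer(n * k_eff)
  for (i in seq_len(n)) {
    o <- order(d2[i, ], seq_len(n))[seq_len(k_eff)]
    dst[((i - 1L) * k_eff + 1L):(i * k_eff)] <- o
  }
  list(edges = cbind(src = src, dst = dst), k_eff = k_eff)
}

#' Build the atomistic protein graph
#'
#' Nodes from [select_protein_nodes()]; features per [feature_layout()];
#' directed Euclidean kNN edges with `k_eff = min(k, n - 1)` and ties
#' broken by node index.
#'
#' @param structure A `gpcr_structure`.
#' @param sites List with `cbs`, `cas` residue keys.
#' @param k Neighbour count (default 64).
#' @param sidechain_table Residue -> sidechain atom map.
#' @return A `protein_graph`: `nodes` (node table), `features`
#'   (n x 34 matrix), `coords` (n x 3), `edges` (E x 2, node indices,
#'   directed src -> dst), `site_mask` (`in_cbs`, `in_cas` logical
#'   vectors), `k_used`.
#' @export
build_protein_graph <- function(structure, sites, k = 64L,
                                sidechain_table = .SIDECHAIN_ATOM) {
  nodes <- select_protein_nodes(structure, sites, sidechain_table)
  if (nrow(nodes) < 2L) stop("protein graph needs >= 2 nodes")
  at <- structure$atom
  akey <- paste(.atom_res_key(at), at$elety)
  idx <- match(paste(nodes$residue_key, nodes$atom_name), akey)
  coords <- cbind(at$x[idx], at$y[idx], at$z[idx])
  if (any(!is.finite(coords))) stop("non-finite node coordinates")

  lay <- feature_layout()$protein
  n <- nrow(nodes)
  feat <- matrix(0, n, 34L)
  aa_idx <- match(nodes$resid, .AA20)
  known <- !is.na(aa_idx)
  feat[cbind(which(known), aa_idx[known])] <- 1
  feat[!known, lay$residue_unknown] <- 1
  in_cbs <- nodes$residue_key %in% sites$cbs
  in_cas <- nodes$residue_key %in% sites$cas
  feat[, lay$cbs_flag] <- as.numeric(in_cbs)
  feat[, lay$cas_flag] <- as.numeric(in_cas)
  feat[, lay$role_ca] <- as.numeric(nodes$role == "CA")
  feat[, lay$role_sidechain] <- as.numeric(nodes$role == "sidechain")
  feat[known, lay$physchem] <- .AA_PROPS[aa_idx[known], ]

  kn <- .knn_edges(coords, k)
  structure(list(nodes = nodes, features = feat, coords = coords,
                 edges = kn$edges,
                 site_mask = list(in_cbs = in_cbs, in_cas = in_cas),
                 k_used = as.integer(k), k_eff = kn$k_eff),
            class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("protein_graph: ", nrow(x$nodes), " nodes (",
      sum(x$site_mask$in_cbs), " cBS, ", sum(x$site_mask$in_cas),
      " cAS), ", nrow(x$edges), " kNN edges (k = ", x$k_used, ")\n",
      sep = "")
  invisible(x)
}

#' Induced cBS subgraph of a protein graph
#'
#' Keeps the binding-site nodes in their original order (so Stage-1
#' signals map back to the full graph by index) and recomputes kNN edges
#' within the subgraph.
#'
#' @param gp A `protein_graph`.
#' @return A `protein_graph` over the cBS nodes; `parent_index` gives each
#'   subgraph node's index in `gp`.
#' @export
cbs_subgraph <- function(gp) {
  keep <- which(gp$site_mask$in_cbs)
  if (!length(keep)) stop("no cBS nodes in protein graph")
  coords <- gp$coords[keep, , drop = FALSE]
  kn <- .knn_edges(coords, gp$k_used)
  structure(list(nodes = gp$nodes[keep, , drop = FALSE],
                 features = gp$features[keep, , drop = FALSE],
                 coords = coords, edges = kn$edges,
                 site_mask = list(in_cbs = gp$site_mask$in_cbs[keep],
                                  in_cas = gp$site_mask$in_cas[keep]),
                 k_used = gp$k_used, k_eff = kn$k_eff,
                 parent_index = keep),
            class = "protein_graph")
}

.ELEMENTS <- c("C", "N", "O", "S", "P", "F", "CL", "BR", "I")

.mol_graph <- function(bonds, n) {
  g <- if (nrow(bonds)) {
    igraph::graph_from_edgelist(as.matrix(bonds[, c("a1", "a2")]),
                                directed = FALSE)
  } else igraph::make_empty_graph(0L, directed = FALSE)
  igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
}

#' Build a ligand graph from SMILES
#'
#' Parses the SMILES, generates one 3D conformer (Open Babel distance
#' geometry + force-field cleanup), and assembles the heavy-atom
#' molecular graph with covalent-bond edges and 19-dimensional node
#' features. Multi-fragment inputs keep the largest fragment with a
#' warning. Conformer generation is deterministic; `seed` is recorded on
#' the graph.
#'
#' @param smiles SMILES string.
#' @param seed Conformer seed tag (recorded; generation is deterministic).
#' @return A `ligand_graph`: `elements`, `features` (n x 19), `coords`
#'   (n x 3), `edges` (undirected bond list with `order`), `smiles`,
#'   `conformer_seed`.
#' @export
build_ligand_graph <- function(smiles, seed = 1L) {
  mol <- .smiles_to_mol3d(smiles, seed)
  el <- toupper(mol$elements)
  heavy <- !(el %in% c("H", "D"))
  h_per_atom <- vapply(seq_along(el), function(i) {
    nb <- c(mol$bonds$a1[mol$bonds$a2 == i], mol$bonds$a2[mol$bonds$a1 == i])
    sum(el[nb] == "H")
  }, numeric(1L))

  idx_map <- cumsum(heavy)
  bonds <- mol$bonds[heavy[mol$bonds$a1] & heavy[mol$bonds$a2], ,
                     drop = FALSE]
  bonds$a1 <- idx_map[bonds$a1]; bonds$a2 <- idx_map[bonds$a2]
  el_h <- el[heavy]
  coords <- mol$coords[heavy, , drop = FALSE]
  charge <- mol$charge[heavy]
  n <- length(el_h)
  if (n == 0L) stop("no heavy atoms in SMILES: ", smiles)

  # largest connected fragment
  g <- .mol_graph(bonds, n)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning("multi-fragment SMILES; keeping largest fragment: ", smiles)
    keep <- comp$membership == which.max(comp$csize)
    remap <- cumsum(keep)
    bonds <- bonds[keep[bonds$a1] & keep[bonds$a2], , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    el_h <- el_h[keep]; coords <- coords[keep, , drop = FALSE]
    charge <- charge[keep]
    h_per_atom_h <- h_per_atom[heavy][keep]
    n <- sum(keep)
    g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a1", "a2")]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  } else {
    h_per_atom_h <- h_per_atom[heavy]
  }

  # ring membership: atoms incident to a non-bridge edge lie on a cycle
  bridges <- igraph::bridges(g)
  ring_edge <- rep(TRUE, nrow(bonds))
  if (length(bridges)) ring_edge[as.integer(bridges)] <- FALSE
  in_ring <- rep(FALSE, n)
  if (nrow(bonds)) {
    in_ring[unique(c(bonds$a1[ring_edge], bonds$a2[ring_edge]))] <- TRUE
  }

  # hybridization from heavy-atom bond orders (kekulized input)
  n_triple <- n_double <- numeric(n)
  for (b in seq_len(nrow(bonds))) {
    o <- bonds$order[b]
    for (a in c(bonds$a1[b], bonds$a2[b])) {
      if (o == 3) n_triple[a] <- n_triple[a] + 1
      if (o == 2) n_double[a] <- n_double[a] + 1
    }
  }
  hyb <- ifelse(n_triple > 0 | n_double >= 2, 1L,
                ifelse(n_double == 1, 2L, 3L))  # 1 = sp, 2 = sp2, 3 = sp3
  aromatic <- in_ring & hyb == 2L
  donor <- el_h %in% c("N", "O") & h_per_atom_h > 0
  acceptor <- el_h %in% c("N", "O")

  lay <- feature_layout()$ligand
  feat <- matrix(0, n, 19L)
  e_idx <- match(el_h, .ELEMENTS)
  e_idx[is.na(e_idx)] <- 10L
  feat[cbind(seq_len(n), e_idx)] <- 1
  feat[cbind(seq_len(n), 10L + hyb)] <- 1
  feat[, lay$aromatic] <- as.numeric(aromatic)
  feat[, lay$ring] <- as.numeric(in_ring)
  feat[, lay$formal_charge] <- charge
  feat[, lay$attached_h] <- h_per_atom_h
  feat[, lay$donor] <- as.numeric(donor)
  feat[, lay$acceptor] <- as.numeric(acceptor)

  structure(list(elements = el_h, features = feat, coords = coords,
                 edges = bonds, smiles = smiles,
                 conformer_seed = as.integer(seed)),
            class = "ligand_graph")
}

#' @export
print.ligand_graph <- function(x, ...) {
  cat("ligand_graph: ", length(x$elements), " heavy atoms, ",
      nrow(x$edges), " bonds [", x$smiles, "]\n", sep = "")
  invisible(x)
}

# Conformers come from seeded ETKDG (distance-geometry embedding with
# experimental torsion preferences), run in batch through the system
# Python with RDKit; results are cached per (SMILES, seed) for the
# session, making graphs bit-reproducible. When that toolchain is
# unavailable, Open Babel's 3D builder stands in (not seedable, so not
# reproducible across sessions).
.conformer_cache <- new.env(parent = emptyenv())

.etkdg_available <- local({
  state <- NULL
  function() {
    if (is.null(state)) {
      state <<- nzchar(Sys.which("python")) &&
        suppressWarnings(system2("python", c("-c", "'import rdkit'"),
                                 stdout = FALSE, stderr = FALSE)) == 0L
    }
    state
  }
})

#' Precompute conformers for a set of SMILES
#'
#' Runs one batch of seeded ETKDG embeddings and fills the session
#' conformer cache used by [build_ligand_graph()]. Calling this before
#' building many graphs avoids one interpreter start per molecule.
#'
#' @param smiles Character vector.
#' @param seed Embedding seed.
#' @return Invisibly, the number of conformers generated.
#' @export
prepare_conformers <- function(smiles, seed = 1L) {
  smiles <- unique(smiles)
  key <- paste0(smiles, "\r", seed)
  todo <- smiles[!vapply(key, exists, logical(1L),
                         envir = .conformer_cache)]
  if (!length(todo) || !.etkdg_available()) return(invisible(0L))
  script <- system.file("scripts", "etkdg_conformers.py",
                        package = "gpcrmoa")
  req <- tempfile(); resp <- tempfile()
  on.exit(unlink(c(req, resp)))
  writeLines(jsonlite::toJSON(list(smiles = todo,
                                   seed = jsonlite::unbox(seed))), req)
  status <- suppressWarnings(system2("python", c(script), stdin = req,
                                     stdout = resp, stderr = FALSE))
  if (!identical(status, 0L)) return(invisible(0L))
  blocks <- jsonlite::read_json(resp)
  n <- 0L
  for (i in seq_along(todo)) {
    b <- blocks[[i]]
    if (!is.null(b)) {
      assign(paste0(todo[i], "\r", seed), b, envir = .conformer_cache)
      n <- n + 1L
    }
  }
  invisible(n)
}

.gen3d <- function(smiles, seed = 1L) {
  key <- paste0(smiles, "\r", seed)
  if (!exists(key, envir = .conformer_cache)) prepare_conformers(smiles,
                                                                 seed)
  if (exists(key, envir = .conformer_cache)) {
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp))
    writeLines(c(get(key, envir = .conformer_cache), "$$$$"), tmp)
    out <- tryCatch(suppressMessages(ChemmineR::read.SDFset(tmp)),
                    error = function(e) NULL)
    if (!is.null(out) && length(out)) return(out)
  }
  tryCatch(ChemmineR::generate3DCoords(
    suppressWarnings(ChemmineR::smiles2sdf(smiles))),
    error = function(e) NULL)
}

# SMILES -> single 3D conformer with explicit hydrogens, via
# Open Babel. Returns elements, coords, bonds (a1, a2, order),
# formal charges.
.smiles_to_mol3d <- function(smiles, seed = 1L) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("unparseable SMILES: ", smiles))
  if (!length(sdf) || !nrow(ChemmineR::atomblock(sdf[[1L]])))
    stop("unparseable SMILES: ", smiles)
  sdf3 <- .gen3d(smiles, seed)
  if (is.null(sdf3)) stop("conformer generation failed: ", smiles)
  m <- sdf3[[1L]]
  ab <- ChemmineR::atomblock(m)
  bb <- ChemmineR::bondblock(m)
  elements <- gsub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  if (nrow(coords) > 1L && all(abs(coords) < 1e-9))
    stop("conformer generation failed: ", smiles)
  chg_code <- if (ncol(ab) >= 5L) ab[, 5L] else rep(0, nrow(ab))
  code_map <- c(`1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2,
                `7` = -3)
  charge <- ifelse(chg_code == 0, 0, code_map[as.character(chg_code)])
  charge[is.na(charge)] <- 0
  bonds <- data.frame(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]),
                      order = as.integer(bb[, 3L]))
  list(elements = elements, coords = coords, bonds = bonds,
       charge = as.numeric(charge))
}

#' Serialize a graph to JSON
#' @param graph A `protein_graph` or `ligand_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  obj <- unclass(graph)
  obj$kind <- class(graph)[1L]
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}
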