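# Label standardization (dose-response values to micromolar, the 10 uM
# binder cutoff, majority-vote mode-of-action resolution) and the
# scaffold-based train/validation/test split: Bemis-Murcko scaffolds,
# ECFP4 fingerprints, Butina clustering, whole-cluster test allocation
# with a class-proportion guard.

#' Standardize a dose-response value to micromolar
#'
#' @param value Positive numeric potency (IC50, EC50, Ki, Kd, ...).
#' @param unit One of `"M"`, `"mM"`, `"uM"`/`"µM"`, `"nM"`, `"pM"`.
#' @return Value in micromolar.
#' @export
standardize_potency <- function(value, unit) {
  if (!is.finite(value) || value <= 0)
    stop("potency must be positive, got ", value)
  fac <- c(M = 1e6, mM = 1e3, uM = 1, nM = 1e-3, pM = 1e-6)
  unit <- sub("µ", "u", unit)
  if (!unit %in% names(fac)) stop("unknown unit: ", unit)
  value * fac[[unit]]
}

#' Binder/nonbinder assignment at the 10 micromolar cutoff
#'
#' Binder iff potency `<= cutoff` (boundary inclusive).
#'
#' @param potency_um Potency in micromolar (positive).
#' @param cutoff Cutoff in micromolar (default 10).
#' @return `"binder"` or `"nonbinder"`.
#' @export
assign_binder <- function(potency_um, cutoff = 10) {
  if (!is.finite(potency_um) || potency_um <= 0)
    stop("potency must be positive")
  if (potency_um <= cutoff) "binder" else "nonbinder"
}

#' Majority-vote mode-of-action resolution
#'
#' Strict-majority winner; exact ties yield no label (status `"tie"`,
#' flagged for manual review rather than auto-resolved).
#'
#' @param annotations Character vector over agonist/antagonist/nonbinder.
#' @return List: `label` (`NA` on tie), `status` (`"unanimous"`,
#'   `"majority"`, `"tie"`).
#' @export
resolve_moa <- function(annotations) {
  if (!length(annotations)) stop("empty annotation list")
  stopifnot(all(annotations %in% c("agonist", "antagonist", "nonbinder")))
  tab <- sort(table(annotations), decreasing = TRUE)
  if (length(tab) == 1L)
    return(list(label = names(tab)[1L], status = "unanimous"))
  if (tab[1L] == tab[2L]) return(list(label = NA_character_,
                                      status = "tie"))
  list(label = names(tab)[1L], status = "majority")
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Ring systems plus connecting linkers: terminal (degree-1) heavy atoms
#' are pruned iteratively. Acyclic molecules return the whole molecule as
#' their own scaffold. The scaffold is reported as a canonical SMILES.
#'
#' @param smiles Input SMILES.
#' @return Canonical scaffold SMILES.
#' @export
murcko_scaffold <- function(smiles) {
  mol <- .smiles_heavy_graph(smiles)
  n <- length(mol$elements)
  bonds <- mol$bonds
  if (!nrow(bonds)) return(.canonical_smiles(smiles))
  keep <- rep(TRUE, n)
  repeat {
    deg <- numeric(n)
    for (b in seq_len(nrow(bonds))) {
      if (keep[bonds$a1[b]] && keep[bonds$a2[b]]) {
        deg[bonds$a1[b]] <- deg[bonds$a1[b]] + 1
        deg[bonds$a2[b]] <- deg[bonds$a2[b]] + 1
      }
    }
    term <- keep & deg <= 1
    if (!any(term)) break
    # everything prunable: acyclic molecule is its own scaffold
    if (!any(keep & !term)) return(.canonical_smiles(smiles))
    keep[term] <- FALSE
  }
  if (!any(keep)) return(.canonical_smiles(smiles))
  .subgraph_smiles(mol, keep)
}

.smiles_heavy_graph <- function(smiles) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) stop("unparseable SMILES: ", smiles))
  m <- sdf[[1L]]
  ab <- ChemmineR::atomblock(m)
  bb <- ChemmineR::bondblock(m)
  el <- toupper(gsub("_.*$", "", rownames(ab)))
  bonds <- data.frame(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]),
                      order = as.integer(bb[, 3L]))
  heavy <- !(el %in% c("H", "D"))
  remap <- cumsum(heavy)
  bonds <- bonds[heavy[bonds$a1] & heavy[bonds$a2], , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  list(elements = el[heavy], bonds = bonds)
}

.canonical_smiles <- function(smiles) {
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN",
                                            paste0(smiles, "\n")),
                  error = function(e) smiles)
  out <- strsplit(trimws(out), "[ \t\n]")[[1L]][1L]
  if (is.na(out) || !nchar(out)) smiles else out
}

# Build a MOL block for the kept atoms and canonicalize via Open Babel.
.subgraph_smiles <- function(mol, keep) {
  idx <- which(keep)
  remap <- match(seq_along(mol$elements), idx)
  bonds <- mol$bonds[keep[mol$bonds$a1] & keep[mol$bonds$a2], ,
                     drop = FALSE]
  el <- mol$elements[idx]
  el <- paste0(substr(el, 1, 1), tolower(substr(el, 2, 10)))
  lines <- c("scaffold", "  gpcrmoa", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     length(idx), nrow(bonds)),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     0, 0, 0, el),
             if (nrow(bonds))
               sprintf("%3d%3d%3d  0  0  0  0", remap[bonds$a1],
                       remap[bonds$a2], bonds$order),
             "M  END", "$$$$")
  out <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN",
                                            paste(lines, collapse = "\n")),
                  error = function(e) NA_character_)
  out <- strsplit(trimws(out), "[ \t\n]")[[1L]][1L]
  if (is.na(out) || !nchar(out)) stop("scaffold canonicalization failed")
  out
}

#' ECFP4 fingerprints for SMILES
#'
#' Extended-connectivity fingerprints (radius 2) computed by Open Babel,
#' folded to `nbits`.
#'
#' @param smiles Character vector.
#' @param nbits Folded length (default 2048).
#' @return Logical matrix (length(smiles) x nbits).
#' @export
ecfp4_fingerprints <- function(smiles, nbits = 2048L) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  fp <- suppressWarnings(ChemmineR::fingerprintOB(sdf, "ECFP4"))
  m <- fp@fpma
  if (!is.matrix(m)) m <- matrix(m, nrow = length(smiles))
  if (ncol(m) > nbits) {
    folds <- split(seq_len(ncol(m)), (seq_len(ncol(m)) - 1L) %% nbits)
    folded <- matrix(FALSE, nrow(m), length(folds))
    for (j in seq_along(folds))
      folded[, j] <- rowSums(m[, folds[[j]], drop = FALSE]) > 0
    m <- folded
  }
  m > 0
}

.tanimoto <- function(a, b) {
  # a, b logical matrices; returns full similarity matrix
  ai <- a * 1; bi <- b * 1
  inter <- tcrossprod(ai, bi)
  na <- rowSums(ai); nb <- rowSums(bi)
  un <- outer(na, nb, "+") - inter
  ifelse(un == 0, 1, inter / un)
}

#' Butina (leader) clustering on fingerprint Tanimoto distance
#'
#' Molecules within `cutoff` Tanimoto distance (`1 - similarity`) of a
#' cluster centroid join that cluster; centroids are chosen by descending
#' neighbour count (ties by index).
#'
#' @param fps Logical fingerprint matrix (rows = molecules).
#' @param cutoff Tanimoto distance cutoff (default 0.4).
#' @return Integer cluster ids (1-based, by cluster size order of
#'   discovery).
#' @export
butina_cluster <- function(fps, cutoff = 0.4) {
  n <- nrow(fps)
  sim <- .tanimoto(fps, fps)
  nbr <- sim >= (1 - cutoff)
  diag(nbr) <- TRUE
  counts <- rowSums(nbr)
  order_idx <- order(-counts, seq_len(n))
  cluster <- integer(n)
  cid <- 0L
  for (i in order_idx) {
    if (cluster[i]) next
    cid <- cid + 1L
    members <- which(nbr[i, ] & cluster == 0L)
    cluster[members] <- cid
  }
  cluster
}

#' Scaffold-based train/validation/test split
#'
#' Bemis-Murcko scaffolds are clustered by Butina on ECFP4 Tanimoto
#' similarity; whole clusters are drawn (seeded random order) into the
#' test set until at least `test_fraction` of records is secured,
#' skipping draws that would push any class's test share above
#' `strat_factor` times its global share. Remaining records are split
#' into train/validation by seeded stratified assignment.
#'
#' @param smiles Character vector of ligand SMILES.
#' @param labels Class labels (nonbinder/agonist/antagonist).
#' @param test_fraction,val_fraction Target fractions (defaults 0.2 of
#'   all records for test; `val_fraction` of the remainder for
#'   validation).
#' @param butina_cutoff Tanimoto distance cutoff (default 0.4).
#' @param strat_factor Stratification guard (default 1.5).
#' @param seed RNG seed.
#' @return A `split_assignment`: data frame (`smiles`, `label`,
#'   `scaffold_smiles`, `cluster_id`, `partition`) plus a `summary`
#'   attribute (partition fractions and class proportions).
#' @export
scaffold_split <- function(smiles, labels, test_fraction = 0.2,
                           val_fraction = 0.2, butina_cutoff = 0.4,
                           strat_factor = 1.5, seed = 1L) {
  stopifnot(length(smiles) == length(labels))
  n <- length(smiles)
  scaffolds <- vapply(smiles, murcko_scaffold, character(1L))
  uniq <- unique(scaffolds)
  fps <- ecfp4_fingerprints(uniq)
  sc_cluster <- butina_cluster(fps, cutoff = butina_cutoff)
  cluster_id <- sc_cluster[match(scaffolds, uniq)]
  n_clusters <- length(unique(cluster_id))
  if (n_clusters < 3L)
    stop("cannot split: need >= 3 scaffold clusters, have ", n_clusters)

  set.seed(seed)
  cl_order <- sample(unique(cluster_id))
  glob_prop <- table(labels) / n
  test_idx <- logical(n)
  target <- test_fraction * n
  overshoot <- 1.25  # "approximately 20%": skip draws far past target
  for (cl in cl_order) {
    if (sum(test_idx) >= target) break
    cand <- test_idx | cluster_id == cl
    if (sum(cand) > overshoot * target) next
    cand_prop <- table(factor(labels[cand], levels = names(glob_prop))) /
      sum(cand)
    if (any(cand_prop > strat_factor * glob_prop)) next
    test_idx <- cand
  }
  if (!any(test_idx)) {
    # no cluster satisfied both guards; fall back to the cluster whose
    # size lands closest to the target
    sizes_cl <- table(cluster_id)
    pick <- names(sizes_cl)[which.min(abs(sizes_cl - target))]
    test_idx <- cluster_id == as.integer(pick)
    warning("allocation guards relaxed: single cluster of ",
            sum(test_idx), " records assigned to test")
  }
  if (sum(test_idx) < target)
    warning("stratification guard limited the test set to ",
            round(100 * sum(test_idx) / n, 1), "% of records")

  partition <- rep(NA_character_, n)
  partition[test_idx] <- "test"
  rest <- which(!test_idx)
  for (cl in unique(labels[rest])) {
    ridx <- rest[labels[rest] == cl]
    nv <- round(val_fraction * length(ridx))
    vidx <- if (nv > 0) sample(ridx, nv) else integer(0)
    partition[ridx] <- "train"
    partition[vidx] <- "val"
  }
  df <- data.frame(smiles = smiles, label = labels,
                   scaffold_smiles = scaffolds, cluster_id = cluster_id,
                   partition = partition, stringsAsFactors = FALSE)
  tab2vec <- function(tb) stats::setNames(as.numeric(tb), names(tb))
  summ <- list(
    fractions = tab2vec(table(partition) / n),
    class_proportions = lapply(split(labels, partition),
                               function(x) tab2vec(table(x) / length(x))))
  attr(df, "summary") <- summ
  class(df) <- c("split_assignment", "data.frame")
  df
}

#' Write a split to TSV + JSON summary
#' @param split A `split_assignment`.
#' @param tsv_path,json_path Output paths (`NULL` to skip).
#' @return `tsv_path`, invisibly.
#' @export
write_split <- function(split, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(split), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(attr(split, "summary"), json_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}
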