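# Mechanistic interpretability: residue importance from the final
# self-attention layer, functional-motif grouping, cross-attention
# binding-residue discrimination (AUROC), an in-silico alanine point
# mutation probe, and coordinate-drift inspection of the equivariant
# layers.

#' Residue importance from self-attention
#'
#' Sums the incoming attention mass (column sums) of the final
#' self-attention layer over its heads, aggregates atom nodes to the
#' residue level (CA + sidechain), averages across predictions, and
#' converts raw scores to rank percentiles in `[0, 1]` (average ranks on
#' ties).
#'
#' @param predictions List of `prediction_output` sharing one receptor
#'   graph.
#' @param gp The shared `protein_graph`.
#' @param layer Which self-attention layer (default: last).
#' @return An `importance_report`: data frame (`residue_key`, `raw`,
#'   `rank_percentile`).
#' @export
residue_importance <- function(predictions, gp, layer = NULL) {
  if (!length(predictions)) stop("empty prediction list")
  n <- nrow(gp$nodes)
  acc <- numeric(n)
  for (p in predictions) {
    if (!length(p$self_attention))
      stop("predictions carry no self-attention weights")
    li <- layer %||% length(p$self_attention)
    heads <- p$self_attention[[li]]
    mass <- Reduce(`+`, lapply(heads, colSums)) / length(heads)
    acc <- acc + mass
  }
  acc <- acc / length(predictions)
  res <- tapply(acc, gp$nodes$residue_key, sum)
  res <- res[unique(gp$nodes$residue_key)]  # structure order
  pct <- (rank(res, ties.method = "average") - 0.5) / length(res)
  structure(data.frame(residue_key = names(res), raw = as.numeric(res),
                       rank_percentile = as.numeric(pct),
                       stringsAsFactors = FALSE),
            class = c("importance_report", "data.frame"))
}

.CANONICAL_MOTIFS <- list(DRY = c("3.49", "3.50", "3.51"),
                          NPxxY = c("7.49", "7.50", "7.53"),
                          CWxP = c("6.47", "6.48", "6.50"),
                          PIF = c("3.40", "5.50", "6.44"))

#' Mean importance of canonical functional motifs
#'
#' Averages residue rank percentiles over each motif's residues present
#' in the receptor; motifs with no resolvable residues are omitted with
#' a warning.
#'
#' @param report An `importance_report`.
#' @param bwmap A `bw_map` for the same receptor.
#' @param motifs Named list of BW-number vectors (canonical defaults:
#'   DRY, NPxxY, CWxP, PIF).
#' @return Named numeric vector of motif mean percentiles.
#' @export
motif_importance <- function(report, bwmap, motifs = .CANONICAL_MOTIFS) {
  out <- numeric(0)
  for (m in names(motifs)) {
    keys <- bw_to_key(bwmap, motifs[[m]])
    keys <- keys[!is.na(keys)]
    vals <- report$rank_percentile[match(keys, report$residue_key)]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) {
      warning("motif ", m, " has no resolvable residues; omitted")
      next
    }
    out[m] <- mean(vals)
  }
  out
}

#' AUROC of cross-attention for binding-residue discrimination
#'
#' Scores each residue by the mean attention mass it receives from
#' ligand queries (ligand-to-protein cross-attention, averaged over
#' heads and ligand nodes, atom nodes summed per residue) and computes
#' the AUROC of that score for separating true binding-site residues,
#' by the Mann-Whitney rank formula with tie correction.
#'
#' @param predictions List of `prediction_output` (or a single one).
#' @param true_cbs Character vector of true binding residue keys.
#' @param g_bs The binding-site `protein_graph` the attention refers to.
#' @param full_graph Optional full `protein_graph`; when given, residues
#'   outside the attended subgraph enter the ranking with zero received
#'   mass (needed when `true_cbs` spans only part of the graph).
#' @return AUROC in `[0, 1]`.
#' @export
binding_residue_auroc <- function(predictions, true_cbs, g_bs,
                                  full_graph = NULL) {
  if (inherits(predictions, "prediction_output"))
    predictions <- list(predictions)
  score <- numeric(nrow(g_bs$nodes))
  for (p in predictions) {
    heads <- p$interaction$cross_attention$ligand_to_protein
    mass <- Reduce(`+`, lapply(heads, colMeans)) / length(heads)
    score <- score + mass
  }
  res_score <- tapply(score, g_bs$nodes$residue_key, sum)
  if (!is.null(full_graph)) {
    all_res <- unique(full_graph$nodes$residue_key)
    full <- stats::setNames(numeric(length(all_res)), all_res)
    full[names(res_score)] <- res_score
    res_score <- full
  }
  labels <- names(res_score) %in% true_cbs
  auroc_mann_whitney(as.numeric(res_score), labels)
}

#' AUROC by the Mann-Whitney rank formula (tie-corrected)
#'
#' @param scores Numeric scores.
#' @param labels Logical (TRUE = positive class).
#' @return AUROC; errors when a class is absent.
#' @export
auroc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("AUROC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' In-silico alanine point mutation probe
#'
#' Replaces one residue by alanine (residue-identity features reset,
#' sidechain node deleted since alanine is CA-only), rebuilds the
#' protein graphs, and rescored every ligand: reports per-ligand binding
#' and agonist probabilities before and after.
#'
#' @param model A `gpcr_model`.
#' @param structure The receptor `gpcr_structure`.
#' @param sites List with `cbs`/`cas` used to build the graphs.
#' @param residue_key Residue to mutate (e.g. the R3.50 key).
#' @param ligands List of `ligand_graph` objects.
#' @param k kNN parameter (default the model's graph default, 64).
#' @return Data frame: `smiles`, `p_bind_before`, `p_bind_after`,
#'   `p_agonist_before`, `p_agonist_after`.
#' @export
mutate_and_rescore <- function(model, structure, sites, residue_key,
                               ligands, k = 64L) {
  keys <- residue_keys(structure)
  if (!residue_key %in% keys)
    stop("residue absent from structure: ", residue_key)
  mut <- structure
  sel <- .atom_res_key(mut$atom) == residue_key
  mut$atom$resid[sel] <- "ALA"
  drop <- sel & mut$atom$elety != "CA"
  mut$atom <- mut$atom[!drop, , drop = FALSE]

  gp0 <- build_protein_graph(structure, sites, k = k)
  gb0 <- cbs_subgraph(gp0)
  gp1 <- build_protein_graph(mut, sites, k = k)
  gb1 <- cbs_subgraph(gp1)
  rows <- lapply(ligands, function(gl) {
    b <- forward_pass(model, gp0, gb0, gl)
    a <- forward_pass(model, gp1, gb1, gl)
    data.frame(smiles = gl$smiles,
               p_bind_before = b$p_bind, p_bind_after = a$p_bind,
               p_agonist_before = b$activity_softmax[1L],
               p_agonist_after = a$activity_softmax[1L])
  })
  do.call(rbind, rows)
}

#' Coordinate drift of the equivariant layers
#'
#' RMSD between the propagated final coordinates and the input
#' coordinates (drift), and optionally an external reference
#' conformation (approach), after Kabsch alignment over all nodes;
#' reported for the cBS, cAS and all-node sets.
#'
#' @param pred A `prediction_output` (with `final_coords`).
#' @param gp The input `protein_graph`.
#' @param reference Optional `gpcr_structure` holding the reference
#'   conformation (matched by residue key + atom name).
#' @return Data frame with one row per region (`all`, `cbs`, `cas`) and
#'   columns `drift_rmsd` and (if reference given) `approach_rmsd`.
#' @export
coordinate_drift <- function(pred, gp, reference = NULL) {
  fin <- pred$final_coords
  inp <- gp$coords
  regions <- list(all = rep(TRUE, nrow(inp)),
                  cbs = gp$site_mask$in_cbs,
                  cas = gp$site_mask$in_cas)
  aligned_rmsd <- function(a, b, mask) {
    fit <- kabsch(a, b)
    moved <- sweep(a %*% t(fit$rotation), 2L, fit$translation, "+")
    sqrt(mean(rowSums((moved - b)[mask, , drop = FALSE]^2)))
  }
  out <- data.frame(region = names(regions),
                    drift_rmsd = vapply(regions, function(m)
                      aligned_rmsd(fin, inp, m), numeric(1L)))
  if (!is.null(reference)) {
    at <- reference$atom
    akey <- paste(.atom_res_key(at), at$elety)
    idx <- match(paste(gp$nodes$residue_key, gp$nodes$atom_name), akey)
    if (all(is.na(idx))) stop("no common atoms with reference")
    ok <- !is.na(idx)
    ref <- cbind(at$x[idx[ok]], at$y[idx[ok]], at$z[idx[ok]])
    out$approach_rmsd <- vapply(regions, function(m)
      aligned_rmsd(fin[ok, , drop = FALSE], ref, m[ok]), numeric(1L))
  }
  out
}

#' Write a per-residue score file for 3D visualization
#'
#' Plain two-column text (`residue_key score`), loadable from molecular
#' viewers.
#'
#' @param report An `importance_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residue_scores <- function(report, path) {
  utils::write.table(report[, c("residue_key", "rank_percentile")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
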