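# Consensus functional sites: the consensus Binding Site (cBS, residues
# within 4.0 A of any bound ligand across holo structures) and the
# consensus Allosteric Site (cAS, top residues by mean apo->holo CA
# displacement). Their union defines the protein subgraph.

#' Consensus binding site across holo structures
#'
#' A residue belongs to the cBS when, in at least one holo structure, the
#' minimum distance between any of its heavy atoms and any ligand heavy
#' atom is `<= radius` (boundary inclusive). Membership is the union over
#' holo structures; provenance counts how many holos support each residue.
#'
#' @param holos List of `list(structure = <gpcr_structure>,
#'   ligand = <HetGroup>)` pairs.
#' @param chain Optional receptor chain restriction.
#' @param radius Contact cutoff in Angstrom (default 4.0).
#' @return List: `cbs` (residue keys, structure order of the first holo),
#'   `provenance` (data frame `key`, `n_holos_supporting`).
#' @export
consensus_binding_site <- function(holos, chain = NULL, radius = 4.0) {
  if (!length(holos)) stop("empty holo list")
  support <- list()
  for (h in holos) {
    s <- h$structure; lig <- h$ligand
    lg <- lig$atoms[lig$atoms$is_heavy, , drop = FALSE]
    if (!nrow(lg)) stop("holo ligand has no heavy atoms")
    at <- s$atom[s$atom$is_heavy, , drop = FALSE]
    if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
    d2 <- outer(at$x, lg$x, "-")^2 + outer(at$y, lg$y, "-")^2 +
      outer(at$z, lg$z, "-")^2
    mind <- sqrt(apply(d2, 1L, min))
    keys <- .atom_res_key(at)
    res_min <- tapply(mind, keys, min)
    hit <- names(res_min)[res_min <= radius]
    for (k in hit) support[[k]] <- (support[[k]] %||% 0L) + 1L
  }
  all_keys <- residue_keys(holos[[1L]]$structure, chain = chain)
  cbs <- intersect(all_keys, names(support))
  extra <- setdiff(names(support), all_keys)  # residues absent from holo 1
  cbs <- c(cbs, sort(extra))
  list(cbs = cbs,
       provenance = data.frame(
         key = cbs,
         n_holos_supporting = vapply(cbs, function(k) support[[k]],
                                     integer(1L)),
         row.names = NULL, stringsAsFactors = FALSE))
}

#' Consensus allosteric site (top residues by mean displacement)
#'
#' Per holo, the structure is superposed onto the apo reference and
#' per-residue CA displacements are computed; the mean over holos ranks
#' residues, and the top `max_size` (default 100) form the cAS. Ties are
#' broken by residue order in the apo structure; receptors with fewer
#' residues return all of them, ranked.
#'
#' @param apo Apo `gpcr_structure`.
#' @param holos List of holo `gpcr_structure`.
#' @param bwmap Optional `bw_map` (BW-number superposition selections).
#' @param superpose_selection Fitting frame (residue keys or BW numbers).
#' @param max_size Maximum cAS size (default 100).
#' @return List: `cas` (ordered residue keys, descending mean
#'   displacement), `provenance` (data frame `key`, `n_holos_supporting`,
#'   `mean_displacement`).
#' @export
consensus_allosteric_site <- function(apo, holos, bwmap = NULL,
                                      superpose_selection = NULL,
                                      max_size = 100L) {
  stopifnot(length(holos) >= 1L)
  keys <- residue_keys(apo)
  acc <- matrix(NA_real_, length(keys), length(holos),
                dimnames = list(keys, NULL))
  for (i in seq_along(holos)) {
    prof <- displacement_profile(apo, holos[[i]], bwmap = NULL,
                                 superpose_selection = superpose_selection)
    idx <- match(names(prof$ca), keys)
    acc[idx[!is.na(idx)], i] <- prof$ca[!is.na(idx)]
  }
  n_sup <- rowSums(!is.na(acc))
  mean_disp <- rowMeans(acc, na.rm = TRUE)
  mean_disp[mean_disp < 1e-9] <- 0  # numerically exact ties stay tied
  defined <- n_sup > 0L
  keys_d <- keys[defined]
  md <- mean_disp[defined]
  # stable order: descending displacement, ties by structure order
  o <- order(-md, seq_along(keys_d))
  take <- utils::head(o, max_size)
  list(cas = keys_d[take],
       provenance = data.frame(
         key = keys_d[take],
         n_holos_supporting = n_sup[defined][take],
         mean_displacement = md[take],
         row.names = NULL, stringsAsFactors = FALSE))
}

#' Serialize consensus sites
#'
#' Writes `{receptor_id, cbs, cas, provenance}` as JSON and, optionally, a
#' BED-like TSV of residue keys with site flags.
#'
#' @param receptor_id Identifier string.
#' @param cbs,cas Residue-key vectors.
#' @param provenance Optional provenance list/data frame.
#' @param json_path,tsv_path Output paths (`NULL` to skip).
#' @return Invisibly, the JSON path.
#' @export
write_sites <- function(receptor_id, cbs, cas, provenance = NULL,
                        json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(receptor_id = receptor_id, cbs = cbs, cas = cas,
           provenance = provenance),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    keys <- union(cbs, cas)
    utils::write.table(
      data.frame(key = keys, in_cbs = keys %in% cbs, in_cas = keys %in% cas),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}

#' Read consensus sites from JSON
#' @param path JSON path written by [write_sites()].
#' @return List with `receptor_id`, `cbs`, `cas`, `provenance`.
#' @export
read_sites <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
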