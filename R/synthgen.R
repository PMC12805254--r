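# Synthetic receptors, ligands and labeled interactions with planted
# geometric and pharmacophoric structure. The receptor is an idealized
# 7-helix bundle whose active state carries the hallmark TM6-outward /
# TM7-inward displacement relative to R3.50; ligands come from a small
# template grammar whose binding/activity labels follow a deterministic
# pharmacophore + size rule. Every downstream module is testable on this
# generator without external data.

#' Synthetic receptor specification
#'
#' @param n_helices Number of transmembrane helices (default 7).
#' @param residues_per_helix Residues per helix (default 30).
#' @param ring_radius Bundle ring radius in Angstrom (at the
#'   intracellular end).
#' @param taper Inward tilt of the helix axes: radius shrinks by this
#'   many Angstrom from the intracellular to the extracellular end,
#'   forming the ligand pocket funnel (default 2.5).
#' @param helix_radius,rise,turn Ideal alpha-helix geometry (2.3 A radius,
#'   1.5 A rise, 100 degrees per residue).
#' @param tm6_shift Outward displacement (Angstrom) of the intracellular
#'   TM6 segment in the active state, along the R3.50-to-TM6-centroid
#'   axis (default 4.0).
#' @param tm7_shift Signed displacement of the intracellular TM7 segment
#'   along the R3.50-to-TM7-centroid axis (default -3.0, i.e. inward).
#' @param tm6_segment,tm7_segment Residue index ranges (within helix)
#'   that move between states; defaults cover the metric anchors.
#' @param pocket_residues Number of pocket residues (default 24).
#' @param pocket_rg Ligand radius-of-gyration gate of the pocket
#'   (Angstrom, default 3.0).
#' @param noise_sigma Per-coordinate Gaussian noise (Angstrom, default 0).
#' @param seed RNG seed for the noise.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_helices = 7L, residues_per_helix = 30L,
                           ring_radius = 9.5, taper = 3.5,
                           helix_radius = 2.3,
                           rise = 1.5, turn = 100, tm6_shift = 4.0,
                           tm7_shift = -3.0, tm6_segment = 1:20,
                           tm7_segment = 1:24, pocket_residues = 24L,
                           pocket_rg = 3.0, noise_sigma = 0, seed = 1L) {
  stopifnot(n_helices >= 7L, residues_per_helix >= 25L,
            pocket_residues <= n_helices * residues_per_helix)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Residue identities planted at BW positions (helix.position, position =
# 29 + within-helix index): conserved motif anchors on a hydrophobic
# background, as in transmembrane helices.
.PLANTED_RESIDUES <- c(
  "3.40" = "ILE", "3.49" = "ASP", "3.50" = "ARG", "3.51" = "TYR",
  "5.50" = "PRO", "6.30" = "GLU", "6.34" = "ARG", "6.44" = "PHE",
  "6.47" = "CYS", "6.48" = "TRP", "6.50" = "PRO",
  "7.49" = "TYR", "7.50" = "LEU", "7.53" = "TYR")

.BACKGROUND_CYCLE <- c("LEU", "ALA", "VAL", "SER", "ILE", "LEU", "GLY",
                       "PHE", "LEU", "THR", "VAL", "ALA")

#' Generate a synthetic two-state receptor
#'
#' Ideal alpha-helical CA traces on a ring, single pseudo-sidechain
#' atoms (named per the functional-atom table, placed radially outward
#' from each helix axis at a residue-size-dependent distance), a planted
#' ligand pocket, and two conformational states: the active state
#' displaces the intracellular TM6 segment outward by `tm6_shift` along
#' the R3.50-to-TM6-centroid axis and the TM7 segment by `tm7_shift`
#' along the R3.50-to-TM7-centroid axis. Both holo states carry a dummy
#' ligand in the pocket; the apo shares the inactive geometry without
#' the ligand. With `noise_sigma = 0` the output is bit-reproducible for
#' any seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `apo`, `holo_active`, `holo_inactive`
#'   (`gpcr_structure`), `bwmap` (`bw_map`), `pocket` (planted pocket
#'   residue keys), `spec`.
#' @export
make_receptor <- function(spec = synthetic_spec()) {
  rp <- spec$residues_per_helix
  n_res <- spec$n_helices * rp
  theta <- 2 * pi * (seq_len(spec$n_helices) - 1L) / spec$n_helices
  rows <- list()
  for (h in seq_len(spec$n_helices)) {
    for (j in seq_len(rp)) {
      rad_j <- spec$ring_radius - spec$taper * (j - 1L) / (rp - 1L)
      cx <- rad_j * cos(theta[h])
      cy <- rad_j * sin(theta[h])
      bw <- paste0(h, ".", 29L + j)
      resid <- .PLANTED_RESIDUES[bw]
      if (is.na(resid))
        resid <- .BACKGROUND_CYCLE[(h + j - 1L) %% length(.BACKGROUND_CYCLE) + 1L]
      alpha <- (j - 1L) * spec$turn * pi / 180 + theta[h]
      ca <- c(cx + spec$helix_radius * cos(alpha),
              cy + spec$helix_radius * sin(alpha),
              (j - 1L) * spec$rise)
      resno <- (h - 1L) * rp + j
      rows[[length(rows) + 1L]] <-
        data.frame(type = "ATOM", elety = "CA", resid = resid,
                   chain = "A", resno = resno, insert = "",
                   x = ca[1L], y = ca[2L], z = ca[3L], o = 1,
                   elesy = "C", helix = h, pos = j, bw = bw,
                   stringsAsFactors = FALSE)
      sc <- .SIDECHAIN_ATOM[resid]
      if (!is.na(sc)) {
        dir_xy <- c(ca[1L] - cx, ca[2L] - cy)
        dir_xy <- dir_xy / sqrt(sum(dir_xy^2))
        len <- 1.5 + 2.5 * .AA_PROPS[resid, "volume"]
        rows[[length(rows) + 1L]] <-
          data.frame(type = "ATOM", elety = sc, resid = resid,
                     chain = "A", resno = resno, insert = "",
                     x = ca[1L] + len * dir_xy[1L],
                     y = ca[2L] + len * dir_xy[2L], z = ca[3L], o = 1,
                     elesy = substr(sc, 1L, 1L), helix = h, pos = j,
                     bw = bw, stringsAsFactors = FALSE)
      }
    }
  }
  at <- do.call(rbind, rows)

  bwmap <- structure(
    data.frame(key = paste0("A:", seq_len(n_res)),
               bw_number = at$bw[!duplicated(at$resno)],
               stringsAsFactors = FALSE),
    class = c("bw_map", "data.frame"))

  # activation displacement axes from the inactive CA geometry
  ca_at <- at[at$elety == "CA", ]
  bw_xyz <- function(bw) unlist(ca_at[match(bw, ca_at$bw), c("x", "y", "z")])
  r350 <- bw_xyz("3.50")
  u6 <- colMeans(rbind(bw_xyz("6.30"), bw_xyz("6.34"), bw_xyz("6.48"))) - r350
  u6 <- u6 / sqrt(sum(u6^2))
  u7 <- colMeans(rbind(bw_xyz("7.49"), bw_xyz("7.50"), bw_xyz("7.53"))) - r350
  u7 <- u7 / sqrt(sum(u7^2))

  at_active <- at
  m6 <- at_active$helix == 6L & at_active$pos %in% spec$tm6_segment
  m7 <- at_active$helix == 7L & at_active$pos %in% spec$tm7_segment
  at_active[m6, c("x", "y", "z")] <-
    at_active[m6, c("x", "y", "z")] +
    rep(spec$tm6_shift * u6, each = sum(m6))
  at_active[m7, c("x", "y", "z")] <-
    at_active[m7, c("x", "y", "z")] +
    rep(spec$tm7_shift * u7, each = sum(m7))

  # planted pocket: every residue inside the contact envelope of the
  # dummy ligand (ligand extent + 4.0 A contact radius), extended with
  # nearest residues up to pocket_residues; the envelope guarantees any
  # 4.0 A ligand-contact residue is a pocket member
  zc <- 0.75 * (rp - 1L) * spec$rise
  pocket_center <- c(0, 0, zc)
  lig <- .dummy_ligand(pocket_center)
  lig_extent <- max(sqrt((lig$atoms$x - pocket_center[1L])^2 +
                           (lig$atoms$y - pocket_center[2L])^2 +
                           (lig$atoms$z - pocket_center[3L])^2))
  both <- rbind(at, at_active)  # contacts can form in either state
  dmin <- sqrt((both$x - pocket_center[1L])^2 +
                 (both$y - pocket_center[2L])^2 +
                 (both$z - pocket_center[3L])^2)
  res_min <- tapply(dmin, both$resno, min)
  env <- as.integer(names(res_min))[res_min <= lig_extent + 4.0]
  extra <- setdiff(as.integer(names(sort(res_min))), env)
  n_extra <- max(0L, spec$pocket_residues - length(env))
  pocket_resno <- c(env, utils::head(extra, n_extra))
  pocket_keys <- paste0("A:", sort(pocket_resno))


  noisy <- function(df, seed_off) {
    if (spec$noise_sigma > 0) {
      set.seed(spec$seed + seed_off)
      df$x <- df$x + stats::rnorm(nrow(df), sd = spec$noise_sigma)
      df$y <- df$y + stats::rnorm(nrow(df), sd = spec$noise_sigma)
      df$z <- df$z + stats::rnorm(nrow(df), sd = spec$noise_sigma)
    }
    df
  }
  mk <- function(atoms, id, with_ligand, seed_off) {
    atoms <- noisy(atoms, seed_off)
    atoms$is_heavy <- TRUE
    structure(list(id = id,
                   atom = atoms[, c("type", "elety", "resid", "chain",
                                    "resno", "insert", "x", "y", "z",
                                    "o", "elesy", "is_heavy")],
                   het = if (with_ligand) list(lig) else list()),
              class = "gpcr_structure")
  }
  list(apo = mk(at, "synthetic_apo", FALSE, 101L),
       holo_active = mk(at_active, "synthetic_active", TRUE, 202L),
       holo_inactive = mk(at, "synthetic_inactive", TRUE, 303L),
       bwmap = bwmap, pocket = pocket_keys, pocket_center = pocket_center,
       spec = spec)
}

.dummy_ligand <- function(center, r1 = 3.0, r2 = 2.2, dz = 1.8) {
  a8 <- 2 * pi * (0:7) / 8
  a6 <- 2 * pi * (0:5) / 6 + pi / 6
  xyz <- rbind(
    cbind(center[1L] + r1 * cos(a8), center[2L] + r1 * sin(a8),
          center[3L]),
    cbind(center[1L] + r2 * cos(a6), center[2L] + r2 * sin(a6),
          center[3L] + dz),
    cbind(center[1L] + r2 * cos(a6), center[2L] + r2 * sin(a6),
          center[3L] - dz),
    matrix(center, 1L))
  atoms <- data.frame(type = "HETATM",
                      elety = paste0("C", seq_len(nrow(xyz))),
                      resid = "LIG", chain = "X", resno = 900L,
                      insert = "", x = xyz[, 1L], y = xyz[, 2L],
                      z = xyz[, 3L], o = 1, elesy = "C",
                      is_heavy = TRUE, stringsAsFactors = FALSE)
  list(comp_id = "LIG", chain = "X", resno = 900L, atoms = atoms)
}

.LIGAND_CORES <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "c1cncnc1",
                   "C1CCOCC1", "C1CCCC1", "c1ccc2ccccc2c1",
                   "C1CCc2ccccc2C1", "c1ccoc1", "C1CCSCC1")

.SUBSTITUENTS <- list(
  activating = c("O", "OC", "OCC", "N", "NC", "NCC"),
  blocking = c("Cl", "ClC", "ClCC", "Br", "BrC", "BrCC"),
  inert = c("C", "CC", "CCC", "COC"))

#' Generate the synthetic ligand set
#'
#' Enumerates drug-like SMILES from a template grammar (ring cores x
#' substituent prefixes): "activating" ligands carry a hydrogen-bond
#' donor substituent (hydroxy/amino), "blocking" ligands a halogen, and
#' "inert" ligands neither. Roughly every fifth functional ligand gets an
#' oversized octyl linker so that it fails the pocket size gate. Classes
#' are balanced to within one of `n/3`; at least 5 distinct Bemis-Murcko
#' scaffolds appear for n >= 30.
#'
#' @param n Number of ligands (>= 3).
#' @param seed Seed (selection order).
#' @return Data frame: `smiles`, `pharmacophore_class`, `oversized`.
#' @export
make_ligand_set <- function(n, seed = 1L) {
  stopifnot(n >= 3L)
  classes <- c("activating", "blocking", "inert")
  combos <- list()
  for (cl in classes) {
    k <- 0L
    for (sub in .SUBSTITUENTS[[cl]]) for (core in .LIGAND_CORES) {
      k <- k + 1L
      oversized <- (k %% 5L == 0L) && cl != "inert"
      link <- if (oversized) "CCCCCCCC" else ""
      combos[[length(combos) + 1L]] <-
        data.frame(smiles = paste0(sub, link, core),
                   pharmacophore_class = cl, oversized = oversized,
                   stringsAsFactors = FALSE)
    }
  }
  pool <- do.call(rbind, combos)
  set.seed(seed)
  out <- list()
  for (i in seq_len(n)) {
    cl <- classes[(i - 1L) %% 3L + 1L]
    sub_pool <- pool[pool$pharmacophore_class == cl, , drop = FALSE]
    row <- sub_pool[((i - 1L) %/% 3L) %% nrow(sub_pool) + 1L, ]
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[sample(n), , drop = FALSE]
}

#' Generate a labeled synthetic dataset
#'
#' Builds the receptor, derives consensus sites and graphs, enumerates
#' ligands and applies the planted label rule: a ligand binds iff its
#' pharmacophore class is not inert AND its conformer's radius of
#' gyration fits the pocket (`rg <= pocket_rg`); bound activating
#' ligands are agonists, bound blocking ligands antagonists, everything
#' else a nonbinder. Ligand graphs are cached per distinct SMILES.
#'
#' @param spec A [synthetic_spec()].
#' @param n_ligands Dataset size.
#' @param seed Seed (ligand order).
#' @param k kNN parameter for the protein graph (default 64).
#' @return List: `receptor` (the [make_receptor()] output), `sites`,
#'   `gp`, `g_bs`, `samples` (list of `list(gp, g_bs, g_l, label,
#'   smiles, rule_trace)`), `manifest` (data frame `receptor_id`,
#'   `smiles`, `label`, `rule_trace`).
#' @export
make_dataset <- function(spec = synthetic_spec(), n_ligands = 600L,
                         seed = 1L, k = 64L) {
  rec <- make_receptor(spec)
  holos <- list(list(structure = rec$holo_active,
                     ligand = rec$holo_active$het[[1L]]),
                list(structure = rec$holo_inactive,
                     ligand = rec$holo_inactive$het[[1L]]))
  stable <- .stable_frame_keys(rec)
  cbs <- consensus_binding_site(holos, chain = "A")
  cas <- consensus_allosteric_site(rec$apo,
                                   list(rec$holo_active,
                                        rec$holo_inactive),
                                   superpose_selection = stable)
  sites <- list(cbs = cbs$cbs, cas = cas$cas)
  gp <- build_protein_graph(rec$apo, sites, k = k)
  g_bs <- cbs_subgraph(gp)

  ligs <- make_ligand_set(n_ligands, seed = seed)
  cache <- new.env(parent = emptyenv())
  samples <- vector("list", n_ligands)
  for (i in seq_len(n_ligands)) {
    smi <- ligs$smiles[i]
    if (is.null(cache[[smi]])) cache[[smi]] <- build_ligand_graph(smi, seed)
    g_l <- cache[[smi]]
    rg <- sqrt(mean(rowSums(sweep(g_l$coords, 2L,
                                  colMeans(g_l$coords))^2)))
    fits <- rg <= spec$pocket_rg
    cl <- ligs$pharmacophore_class[i]
    binds <- cl != "inert" && fits
    label <- if (!binds) interaction_label(0L)
             else interaction_label(1L, if (cl == "activating") "agonist"
                                        else "antagonist")
    trace <- sprintf("class=%s rg=%.2f gate=%s -> %s", cl, rg,
                     if (fits) "fits" else "too_large",
                     .label_class(label))
    samples[[i]] <- list(gp = gp, g_bs = g_bs, g_l = g_l, label = label,
                         smiles = smi, rule_trace = trace)
  }
  manifest <- data.frame(
    receptor_id = "synthetic_gpcr",
    smiles = ligs$smiles,
    label = vapply(samples, function(s) .label_class(s$label),
                   character(1L)),
    rule_trace = vapply(samples, `[[`, character(1L), "rule_trace"),
    stringsAsFactors = FALSE)
  list(receptor = rec, sites = sites, gp = gp, g_bs = g_bs,
       samples = samples, manifest = manifest)
}

# Residues of the helices untouched by the activation shift: a stable
# superposition frame for displacement analyses.
.stable_frame_keys <- function(rec) {
  rp <- rec$spec$residues_per_helix
  stable_h <- setdiff(seq_len(rec$spec$n_helices), c(6L, 7L))
  resno <- unlist(lapply(stable_h, function(h) (h - 1L) * rp + seq_len(rp)))
  paste0("A:", resno)
}
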