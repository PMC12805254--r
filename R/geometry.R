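# Activation-geometry signatures of GPCRs: TM6-outward / TM7-inward
# distance metrics around the conserved R3.50 switch, apo->holo
# displacement profiles, allosteric-complexity counts, and an exhaustive
# axis-aligned (root-node) split probe over geometry feature tables.

.TM6_ANCHORS <- c("6.30", "6.34", "6.48")
.TM7_ANCHORS <- c("7.49", "7.50", "7.53")

#' TM6/TM7 activation-state distance metrics
#'
#' `dist_tm6` is the CA distance from R3.50 to the unweighted centroid of
#' the CA atoms at BW positions 6.30, 6.34 and 6.48 (the acidic/basic and
#' toggle anchors of TM6); `dist_tm7` the analogous distance to the
#' centroid of 7.49, 7.50 and 7.53. Anchors are matched by BW number
#' regardless of residue identity. A metric with fewer than two of its
#' three anchors present is reported as `NA` (undefined), not an error.
#'
#' @param structure A `gpcr_structure`.
#' @param bwmap A [load_bw_map()] result covering the receptor chain.
#' @return List: `dist_tm6`, `dist_tm7` (Angstrom or `NA`), and
#'   `residues_used` (BW numbers entering each centroid).
#' @export
activation_metrics <- function(structure, bwmap) {
  ref_key <- bw_to_key(bwmap, "3.50")
  if (is.na(ref_key)) stop("reference residue missing: 3.50 not in BW map")
  ref <- ca_coords(structure, ref_key)
  if (any(!is.finite(ref))) stop("reference residue missing: no CA for 3.50")
  one <- function(anchors) {
    keys <- bw_to_key(bwmap, anchors)
    xyz <- ca_coords(structure, keys[!is.na(keys)])
    ok <- stats::complete.cases(xyz)
    used <- anchors[!is.na(keys)][ok]
    if (sum(ok) < 2L) return(list(d = NA_real_, used = used))
    centroid <- colMeans(xyz[ok, , drop = FALSE])
    list(d = sqrt(sum((centroid - ref)^2)), used = used)
  }
  tm6 <- one(.TM6_ANCHORS); tm7 <- one(.TM7_ANCHORS)
  list(dist_tm6 = tm6$d, dist_tm7 = tm7$d,
       residues_used = list(tm6 = tm6$used, tm7 = tm7$used))
}

#' Per-residue displacement between two conformational states
#'
#' Superposes `holo` onto `apo` over `superpose_selection` (Kabsch fit on
#' CA atoms), then reports per-residue CA displacement and the maximum
#' heavy-atom displacement, for residues present in both states.
#'
#' @param apo,holo `gpcr_structure` objects of the same receptor.
#' @param bwmap Optional `bw_map`; when given, profile names are BW
#'   numbers where mapped.
#' @param superpose_selection Residue keys (or BW numbers with `bwmap`)
#'   defining the fitting frame; default all shared residues.
#' @return List: `ca` (named vector of CA displacements, Angstrom),
#'   `heavy_atom_max` (named vector of max heavy-atom displacements),
#'   `fit_rmsd`.
#' @export
displacement_profile <- function(apo, holo, bwmap = NULL,
                                 superpose_selection = NULL) {
  fit <- superpose(holo, apo, selection = superpose_selection,
                   bwmap = bwmap)
  holo_f <- transform_structure(holo, fit$rotation, fit$translation)
  shared <- intersect(residue_keys(apo), residue_keys(holo_f))
  ca_a <- ca_coords(apo, shared); ca_h <- ca_coords(holo_f, shared)
  ok <- stats::complete.cases(ca_a) & stats::complete.cases(ca_h)
  ca_disp <- sqrt(rowSums((ca_h - ca_a)^2))[ok]

  hmax <- vapply(shared[ok], function(k) {
    aa <- apo$atom[.atom_res_key(apo$atom) == k & apo$atom$is_heavy, ,
                   drop = FALSE]
    hh <- holo_f$atom[.atom_res_key(holo_f$atom) == k &
                        holo_f$atom$is_heavy, , drop = FALSE]
    common <- intersect(aa$elety, hh$elety)
    if (!length(common)) return(NA_real_)
    ia <- match(common, aa$elety); ih <- match(common, hh$elety)
    max(sqrt((aa$x[ia] - hh$x[ih])^2 + (aa$y[ia] - hh$y[ih])^2 +
               (aa$z[ia] - hh$z[ih])^2))
  }, numeric(1L))

  nm <- shared[ok]
  if (!is.null(bwmap)) {
    bw <- key_to_bw(bwmap, nm)
    nm <- ifelse(is.na(bw), nm, bw)
  }
  names(ca_disp) <- nm; names(hmax) <- nm
  list(ca = ca_disp, heavy_atom_max = hmax, fit_rmsd = fit$rmsd)
}

#' Allosteric-site residues and complexity flag
#'
#' A residue belongs to the allosteric site (AS) when, in at least one
#' holo state, one of its heavy atoms moves strictly more than
#' `threshold` Angstrom relative to the apo reference (after
#' superposition), and the residue is not part of the direct binding
#' site. Receptors with more than 200 AS residues are flagged
#' allosterically complex.
#'
#' @param apo Apo reference `gpcr_structure`.
#' @param holos List of holo `gpcr_structure` objects.
#' @param cbs Character vector of binding-site residue keys to exclude.
#' @param bwmap,superpose_selection Passed to [displacement_profile()].
#' @param threshold Strict displacement cutoff (default 4.0 Angstrom).
#' @param complex_cutoff AS count above which the receptor is flagged.
#' @return List: `as_residues` (keys), `count`, `complex_flag`.
#' @export
allosteric_site <- function(apo, holos, cbs = character(),
                            bwmap = NULL, superpose_selection = NULL,
                            threshold = 4.0, complex_cutoff = 200L) {
  stopifnot(length(holos) >= 1L)
  movers <- character()
  for (h in holos) {
    prof <- displacement_profile(apo, h, bwmap = NULL,
                                 superpose_selection = superpose_selection)
    hm <- prof$heavy_atom_max
    movers <- union(movers, names(hm)[!is.na(hm) & hm > threshold])
  }
  as_res <- setdiff(movers, cbs)
  as_res <- as_res[order(match(as_res, residue_keys(apo)))]
  list(as_residues = as_res, count = length(as_res),
       complex_flag = length(as_res) > complex_cutoff)
}

#' Two-sided Welch's t-test
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value from the exact Student-t distribution. When both
#' groups are constant the convention is p = 1 for equal means and p = 0
#' otherwise.
#'
#' @param a,b Numeric vectors (length >= 2 each).
#' @return List: `t`, `df`, `p_two_sided`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t requires at least 2 observations per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p_two_sided = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p_two_sided = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_two_sided = ht$p.value)
}

#' Assemble a geometry feature table
#'
#' Rows are structures; columns are intra-receptor CA distances
#' (`Dist_<bwA>_<bwB>`) for requested BW pairs and per-residue CA
#' displacements from an apo reference (`Disp_<bw>`), plus a `label`
#' column.
#'
#' @param structures List of `gpcr_structure`.
#' @param labels Character vector (`agonist_bound` / `antagonist_bound`).
#' @param bwmaps A single `bw_map` shared by all structures, or a list.
#' @param dist_pairs 2-column character matrix of BW pairs.
#' @param apo Optional apo reference for displacement columns.
#' @param superpose_selection Frame for displacement superposition.
#' @return `data.frame` with unique feature columns and a `label` column.
#' @export
geometry_feature_table <- function(structures, labels, bwmaps,
                                   dist_pairs = NULL, apo = NULL,
                                   superpose_selection = NULL) {
  stopifnot(length(structures) == length(labels))
  if (inherits(bwmaps, "bw_map"))
    bwmaps <- rep(list(bwmaps), length(structures))
  rows <- lapply(seq_along(structures), function(i) {
    s <- structures[[i]]; bm <- bwmaps[[i]]
    out <- list()
    if (!is.null(dist_pairs)) {
      for (r in seq_len(nrow(dist_pairs))) {
        k1 <- bw_to_key(bm, dist_pairs[r, 1L])
        k2 <- bw_to_key(bm, dist_pairs[r, 2L])
        d <- if (is.na(k1) || is.na(k2)) NA_real_ else
          sqrt(sum((ca_coords(s, k1) - ca_coords(s, k2))^2))
        out[[paste0("Dist_", dist_pairs[r, 1L], "_", dist_pairs[r, 2L])]] <- d
      }
    }
    if (!is.null(apo)) {
      prof <- displacement_profile(apo, s, bwmap = bm,
                                   superpose_selection = superpose_selection)
      disp <- prof$ca[grepl("^[0-9]+\\.[0-9]+$", names(prof$ca))]
      names(disp) <- paste0("Disp_", names(disp))
      out <- c(out, as.list(disp))
    }
    out
  })
  cols <- unique(unlist(lapply(rows, names)))
  tab <- as.data.frame(lapply(cols, function(cn)
    vapply(rows, function(r) r[[cn]] %||% NA_real_, numeric(1L))))
  names(tab) <- cols
  tab$label <- labels
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Best single axis-aligned split of a labeled feature table
#'
#' Exhaustively scans every feature and every midpoint between
#' consecutive distinct sorted values, maximizing the decrease in Gini
#' impurity (the root node of a classification tree). Ties are broken by
#' feature name, then by the smaller threshold. `fraction_separated` is
#' the fraction of rows landing in pure children under the best split.
#'
#' @param table Data frame of numeric features plus a `label` column with
#'   exactly two classes.
#' @return List: `feature_name`, `threshold`, `gini_gain`,
#'   `fraction_separated`.
#' @export
best_axis_split <- function(table) {
  stopifnot(nrow(table) >= 2L, "label" %in% names(table))
  y <- as.character(table$label)
  if (length(unique(y)) < 2L) stop("degenerate labels: single class")
  feats <- sort(setdiff(names(table), "label"))
  n <- nrow(table)
  p <- mean(y == unique(y)[1L])
  gini_parent <- 1 - p^2 - (1 - p)^2
  best <- list(feature_name = feats[1L], threshold = NA_real_,
               gini_gain = 0, fraction_separated = 0)
  for (f in feats) {
    v <- table[[f]]
    ok <- !is.na(v)
    if (sum(ok) < 2L) next
    vo <- v[ok]; yo <- y[ok]
    o <- order(vo)
    vs <- vo[o]; ys <- yo[o] == unique(y)[1L]
    distinct <- which(diff(vs) > 0)
    if (!length(distinct)) next
    cum1 <- cumsum(ys)
    nl <- distinct
    n1l <- cum1[distinct]
    ntot <- length(vs); n1 <- sum(ys)
    nr <- ntot - nl; n1r <- n1 - n1l
    gl <- 1 - (n1l / nl)^2 - ((nl - n1l) / nl)^2
    gr <- 1 - (n1r / nr)^2 - ((nr - n1r) / nr)^2
    gain <- gini_parent - (nl / ntot) * gl - (nr / ntot) * gr
    thr <- (vs[distinct] + vs[distinct + 1L]) / 2
    # features are scanned in sorted name order and thresholds ascending,
    # so keeping the first strict improvement realizes the documented
    # tie-break (feature name, then smaller threshold)
    for (j in seq_along(distinct)) {
      cand_gain <- gain[j]
      better <- cand_gain > best$gini_gain + 1e-12 ||
        (is.na(best$threshold) && cand_gain >= best$gini_gain)
      if (better) {
        pure_l <- if (gl[j] == 0) nl[j] else 0L
        pure_r <- if (gr[j] == 0) nr[j] else 0L
        best <- list(feature_name = f, threshold = thr[j],
                     gini_gain = cand_gain,
                     fraction_separated = (pure_l + pure_r) / ntot)
      }
    }
  }
  best
}

#' Write/read a geometry feature table as CSV
#' @param table Feature table from [geometry_feature_table()].
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
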