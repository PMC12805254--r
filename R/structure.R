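# Structural input handling: mmCIF/PDB parsing, chain selection by local
# alignment, ligand extraction, rigid-body superposition, and
# Ballesteros-Weinstein (BW) residue-number tables.

#' Parse a macromolecular structure file
#'
#' Reads a PDB or mmCIF file into a `gpcr_structure`: polymer chains
#' (ordered residues with heavy/hydrogen-flagged atoms) plus HETATM groups.
#' Alternate locations are resolved to the highest-occupancy copy (ties go
#' to altloc `"A"`, then first record); hydrogens are retained but flagged.
#'
#' @param path Path to the structure file.
#' @param dialect `"pdb"` or `"mmcif"`. Defaults from the file extension.
#' @return An object of class `gpcr_structure` with elements `id`, `atom`
#'   (polymer atom table), and `het` (list of HETATM groups, each with
#'   `comp_id` and an `atoms` table).
#' @export
parse_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (dialect == "mmcif") {
    at <- tryCatch(.read_mmcif_atoms(path),
                   error = function(e)
                     stop("parse error in ", basename(path), " [mmcif]: ",
                          conditionMessage(e)))
  } else {
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE,
                                    rm.alt = FALSE),
                    error = function(e)
                      stop("parse error in ", basename(path), " [pdb]: ",
                           conditionMessage(e)))
    at <- pdb$atom
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- "A"
  if (is.null(at$o) || all(is.na(at$o))) at$o <- 1
  at$o[is.na(at$o)] <- 1
  at$elesy <- .infer_element(at$elesy, at$elety)

  at <- .resolve_altloc(at)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("parse error: non-finite coordinates in ", basename(path))

  water <- c("HOH", "DOD", "WAT")
  poly <- at[at$type == "ATOM" & !(at$resid %in% water), , drop = FALSE]
  hets <- at[at$type == "HETATM" & !(at$resid %in% water), , drop = FALSE]
  if (nrow(poly) == 0L) stop("no polymer chains in ", basename(path))

  ord <- order(match(poly$chain, unique(poly$chain)), poly$resno,
               poly$insert)
  poly <- poly[ord, , drop = FALSE]
  poly$is_heavy <- !(toupper(poly$elesy) %in% c("H", "D"))
  hets$is_heavy <- !(toupper(hets$elesy) %in% c("H", "D"))

  het_groups <- list()
  if (nrow(hets) > 0L) {
    key <- paste(hets$chain, hets$resno, hets$resid, sep = "|")
    for (k in unique(key)) {
      sub <- hets[key == k, , drop = FALSE]
      het_groups[[length(het_groups) + 1L]] <-
        list(comp_id = sub$resid[1L], chain = sub$chain[1L],
             resno = sub$resno[1L], atoms = sub)
    }
  }
  structure(list(id = sub("\\.[^.]*$", "", basename(path)),
                 atom = poly, het = het_groups),
            class = "gpcr_structure")
}

# Compact atom_site-loop reader for coordinate mmCIF files. Returns a
# bio3d-style atom table (type, elety, resid, chain, resno, insert,
# x, y, z, o, alt, elesy).
.read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tag_idx <- grep("^_atom_site\\.", lines)
  if (!length(tag_idx)) stop("no _atom_site loop (category missing)")
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  start <- max(tag_idx) + 1L
  rows <- character()
  for (i in start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_") || startsWith(ln, "data_")) break
    rows <- c(rows, ln)
  }
  if (!length(rows)) stop("empty _atom_site loop")
  fields <- strsplit(rows, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != length(tags)))
    stop("malformed _atom_site row at line ",
         start + which(nf != length(tags))[1L] - 1L)
  m <- do.call(rbind, fields)
  colnames(m) <- tags
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% tags) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  clean <- function(v) ifelse(v %in% c("?", "."), "", v)
  num <- function(v) suppressWarnings(as.numeric(v))
  out <- data.frame(
    type = pick("group_PDB"),
    elety = clean(pick("auth_atom_id", "label_atom_id")),
    resid = clean(pick("auth_comp_id", "label_comp_id")),
    chain = clean(pick("auth_asym_id", "label_asym_id")),
    resno = as.integer(num(pick("auth_seq_id", "label_seq_id"))),
    insert = clean(pick("pdbx_PDB_ins_code")),
    x = num(pick("Cartn_x")), y = num(pick("Cartn_y")),
    z = num(pick("Cartn_z")),
    o = num(pick("occupancy")),
    alt = clean(pick("label_alt_id")),
    elesy = clean(pick("type_symbol")),
    stringsAsFactors = FALSE)
  if (any(is.na(out$x) | is.na(out$y) | is.na(out$z)))
    stop("non-numeric coordinates in _atom_site (Cartn_* category)")
  out
}

.infer_element <- function(elesy, elety) {
  miss <- is.na(elesy) | elesy == ""
  if (any(miss)) {
    guess <- sub("^[0-9]*", "", elety[miss])
    two <- substr(guess, 1, 2) %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")
    elesy[miss] <- ifelse(two, substr(guess, 1, 2), substr(guess, 1, 1))
  }
  elesy
}

# Keep one altloc per (chain, resno, insert, atom name): highest occupancy,
# ties broken by altloc "A" then record order.
.resolve_altloc <- function(at) {
  if (all(at$alt == "")) return(at)
  key <- paste(at$type, at$chain, at$resno, at$insert, at$elety, sep = "|")
  pref <- order(key, -at$o, at$alt != "A", seq_len(nrow(at)))
  at2 <- at[pref, , drop = FALSE]
  at2 <- at2[!duplicated(paste(at2$type, at2$chain, at2$resno, at2$insert,
                               at2$elety, sep = "|")), , drop = FALSE]
  at2[order(match(rownames(at2), rownames(at))), , drop = FALSE]
}

#' @export
print.gpcr_structure <- function(x, ...) {
  ch <- unique(x$atom$chain)
  cat("gpcr_structure '", x$id, "': ", length(ch), " chain(s) [",
      paste(ch, collapse = ","), "], ",
      length(unique(residue_keys(x))), " residues, ",
      length(x$het), " HETATM group(s)\n", sep = "")
  invisible(x)
}

#' Residue keys of a structure
#'
#' Keys are `"<chain>:<auth_seq_id><insert>"`, e.g. `"A:350"`; insertion
#' codes are appended as text.
#' @param structure A `gpcr_structure`.
#' @param chain Optional chain filter.
#' @return Character vector of unique residue keys in structure order.
#' @export
residue_keys <- function(structure, chain = NULL) {
  at <- structure$atom
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  unique(paste0(at$chain, ":", at$resno, at$insert))
}

.atom_res_key <- function(at) paste0(at$chain, ":", at$resno, at$insert)

#' Alpha-carbon coordinates by residue key
#' @param structure A `gpcr_structure`.
#' @param keys Residue keys; default all.
#' @return Matrix (length(keys) x 3) of CA coordinates; `NA` rows where the
#'   residue or its CA is absent.
#' @export
ca_coords <- function(structure, keys = residue_keys(structure)) {
  at <- structure$atom
  ca <- at[at$elety == "CA", , drop = FALSE]
  idx <- match(keys, .atom_res_key(ca))
  out <- cbind(ca$x[idx], ca$y[idx], ca$z[idx])
  rownames(out) <- keys
  out
}

.three2one <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
                MSE = "M", SEC = "U", PYL = "O")

#' One-letter sequence of a chain
#' @param structure A `gpcr_structure`.
#' @param chain Chain identifier.
#' @return Single string; unknown residues become `"X"`.
#' @export
chain_sequence <- function(structure, chain) {
  at <- structure$atom[structure$atom$chain == chain, , drop = FALSE]
  res <- at$resid[!duplicated(paste0(at$resno, at$insert))]
  one <- .three2one[res]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Select the receptor chain by local sequence alignment
#'
#' Aligns every polymer chain against a reference sequence with
#' Smith-Waterman local alignment (BLOSUM62, affine gaps: opening 11,
#' extension 1 per gapped position) and returns the best-scoring chain.
#' Ties are broken by lexicographic chain id.
#'
#' @param structure A `gpcr_structure`.
#' @param ref_seq Reference amino-acid sequence (one-letter string).
#' @param min_identity Identity floor below which no chain is accepted.
#' @param gap_opening,gap_extension Affine gap penalties (positive).
#' @return List with `chain_id` and `alignment` (score, spans as half-open
#'   0-based intervals, identity_fraction, aligned_pairs).
#' @export
select_receptor_chain <- function(structure, ref_seq, min_identity = 0.3,
                                  gap_opening = 11, gap_extension = 1) {
  stopifnot(nchar(ref_seq) > 0)
  chains <- unique(structure$atom$chain)
  best <- NULL
  for (ch in sort(chains)) {
    seq <- chain_sequence(structure, ch)
    aln <- smith_waterman(seq, ref_seq, gap_opening, gap_extension)
    if (is.null(best) || aln$score > best$alignment$score)
      best <- list(chain_id = ch, alignment = aln)
  }
  if (best$alignment$score <= 0 ||
      best$alignment$identity_fraction < min_identity)
    stop("no matching receptor chain (best identity ",
         signif(best$alignment$identity_fraction, 3), ")")
  best
}

#' Smith-Waterman local alignment (BLOSUM62)
#'
#' Thin wrapper over [Biostrings::pairwiseAlignment()] returning the score,
#' aligned spans, identity fraction and residue-index pairs. A gap of
#' length L is penalized `gap_opening + L * gap_extension`.
#'
#' @param query,target Amino-acid strings.
#' @param gap_opening,gap_extension Positive affine gap penalties.
#' @return List: `score`, `query_span`, `target_span` (half-open, 0-based),
#'   `identity_fraction`, `aligned_pairs` (matrix of 1-based index pairs,
#'   strictly increasing in both columns).
#' @export
smith_waterman <- function(query, target, gap_opening = 11,
                           gap_extension = 1) {
  query <- toupper(gsub("[^A-Za-z]", "", query))
  target <- toupper(gsub("[^A-Za-z]", "", target))
  blosum62 <- .load_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(target),
    type = "local", substitutionMatrix = blosum62,
    gapOpening = gap_opening, gapExtension = gap_extension)
  gq <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  gt <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  qi <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  ti <- Biostrings::start(Biostrings::subject(pa)) - 1L
  pairs <- matrix(integer(0), 0L, 2L)
  n_match <- 0L
  for (k in seq_along(gq)) {
    q_gap <- gq[k] == "-"
    t_gap <- gt[k] == "-"
    if (!q_gap) qi <- qi + 1L
    if (!t_gap) ti <- ti + 1L
    if (!q_gap && !t_gap) {
      pairs <- rbind(pairs, c(qi, ti))
      if (gq[k] == gt[k]) n_match <- n_match + 1L
    }
  }
  list(score = as.numeric(Biostrings::score(pa)),
       query_span = c(Biostrings::start(Biostrings::pattern(pa)) - 1L,
                      Biostrings::end(Biostrings::pattern(pa))),
       target_span = c(Biostrings::start(Biostrings::subject(pa)) - 1L,
                       Biostrings::end(Biostrings::subject(pa))),
       identity_fraction = if (nrow(pairs)) n_match / nrow(pairs) else 0,
       aligned_pairs = pairs)
}

.load_blosum62 <- function() {
  env <- new.env()
  pkg <- if (requireNamespace("pwalign", quietly = TRUE) &&
             "BLOSUM62" %in% utils::data(package = "pwalign")$results[, 3L])
    "pwalign" else "Biostrings"
  utils::data("BLOSUM62", package = pkg, envir = env)
  get("BLOSUM62", envir = env)
}

# Default HETATM exclusion list: waters, common ions, buffers and
# cryoprotectants routinely present in experimental structures.
.het_exclude_default <- c(
  "HOH", "DOD", "WAT", "NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE",
  "CU", "NI", "CO", "CD", "HG", "BR", "IOD", "SO4", "PO4", "GOL", "EDO",
  "PEG", "PGE", "PG4", "MPD", "DMS", "ACT", "FMT", "TRS", "EPE", "MES",
  "BME", "DTT", "NAG", "BMA", "MAN", "OLA", "OLC", "CLR", "CHS", "PLM")

#' Extract drug-like ligands from HETATM records
#'
#' Filters out waters, entries on the exclusion list (ions, buffers,
#' lipids, sugars), and groups with fewer than `min_heavy` heavy atoms.
#' Record order is preserved.
#'
#' @param structure A `gpcr_structure`.
#' @param exclude Component ids to drop (defaults ship with the package).
#' @param min_heavy Minimum heavy-atom count (default 6).
#' @return List of HETATM groups (`comp_id`, `atoms`).
#' @export
extract_ligands <- function(structure, exclude = .het_exclude_default,
                            min_heavy = 6L) {
  keep <- vapply(structure$het, function(h) {
    !(h$comp_id %in% exclude) && sum(h$atoms$is_heavy) >= min_heavy
  }, logical(1L))
  structure$het[keep]
}

#' Rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` over paired CA atoms of
#' a residue selection. Selection entries may be residue keys or BW
#' numbers (resolved through `bwmap`).
#'
#' @param mobile,reference `gpcr_structure` objects.
#' @param selection Character vector of residue keys (or BW numbers if
#'   `bwmap` given); default: all residues shared by both structures.
#' @param bwmap Optional [load_bw_map()] result for BW-number selections.
#' @return List `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (post-fit, over the selection). Transformed mobile coordinates are
#'   `x %*% t(rotation) + translation`.
#' @export
superpose <- function(mobile, reference, selection = NULL, bwmap = NULL) {
  if (is.null(selection))
    selection <- intersect(residue_keys(mobile), residue_keys(reference))
  if (!is.null(bwmap)) {
    bw <- grepl("^[0-9]+\\.[0-9]+$", selection)
    selection[bw] <- bw_to_key(bwmap, selection[bw])
  }
  xm <- ca_coords(mobile, selection)
  xr <- ca_coords(reference, selection)
  ok <- stats::complete.cases(xm) & stats::complete.cases(xr)
  if (sum(ok) < 3L) stop("insufficient correspondence: ", sum(ok),
                         " paired CA atoms (need >= 3)")
  fit <- kabsch(xm[ok, , drop = FALSE], xr[ok, , drop = FALSE])
  moved <- xm[ok, , drop = FALSE] %*% t(fit$rotation)
  moved <- sweep(moved, 2L, fit$translation, "+")
  fit$rmsd <- sqrt(mean(rowSums((moved - xr[ok, , drop = FALSE])^2)))
  fit
}

#' Kabsch least-squares rotation/translation
#' @param x,y Matrices (n x 3); returns the transform mapping `x` onto `y`.
#' @return List with `rotation` and `translation`.
#' @export
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = rot, translation = as.numeric(cy - rot %*% cx))
}

#' Apply a rigid transform to a structure
#' @param structure A `gpcr_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 vector.
#' @return Transformed `gpcr_structure` (polymer and HETATM coordinates).
#' @export
transform_structure <- function(structure, rotation, translation) {
  tx <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rotation)
    xyz <- sweep(xyz, 2L, translation, "+")
    df$x <- xyz[, 1L]; df$y <- xyz[, 2L]; df$z <- xyz[, 3L]
    df
  }
  structure$atom <- tx(structure$atom)
  structure$het <- lapply(structure$het, function(h) {
    h$atoms <- tx(h$atoms); h
  })
  structure
}

#' Load a Ballesteros-Weinstein numbering table
#'
#' Reads a TSV with columns `chain_id`, `auth_seq_id`, `bw_number` and
#' restricts it to residues present in the structure. BW numbers must be
#' unique (injective map); rows referencing absent residues are skipped
#' with a warning.
#'
#' @param path TSV path.
#' @param structure A `gpcr_structure`.
#' @return A `bw_map`: data frame (`key`, `bw_number`) with lookup both ways.
#' @export
load_bw_map <- function(path, structure) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("chain_id", "auth_seq_id", "bw_number")
  if (!all(need %in% names(tb)))
    stop("BW table must have columns: ", paste(need, collapse = ", "))
  if (!all(grepl("^[0-9]+\\.[0-9]+$", tb$bw_number)))
    stop("malformed BW number(s): ",
         paste(tb$bw_number[!grepl("^[0-9]+\\.[0-9]+$", tb$bw_number)],
               collapse = ", "))
  if (anyDuplicated(tb$bw_number))
    stop("non-injective BW map: duplicated ",
         paste(unique(tb$bw_number[duplicated(tb$bw_number)]),
               collapse = ", "))
  key <- paste0(tb$chain_id, ":", tb$auth_seq_id)
  present <- key %in% residue_keys(structure)
  if (any(!present)) {
    warning(sum(!present), " BW row(s) reference absent residues; skipped")
    tb <- tb[present, , drop = FALSE]; key <- key[present]
  }
  if (anyDuplicated(key)) stop("non-injective BW map: duplicated residue key")
  structure(data.frame(key = key, bw_number = tb$bw_number,
                       stringsAsFactors = FALSE), class = c("bw_map",
                                                            "data.frame"))
}

#' BW number to residue key (and back)
#' @param bwmap A `bw_map`.
#' @param bw BW numbers (e.g. `"3.50"`).
#' @return Residue keys (`NA` where unmapped).
#' @export
bw_to_key <- function(bwmap, bw) bwmap$key[match(bw, bwmap$bw_number)]

#' @rdname bw_to_key
#' @param keys Residue keys.
#' @export
key_to_bw <- function(bwmap, keys) bwmap$bw_number[match(keys, bwmap$key)]

#' Write a structure to PDB or mmCIF
#'
#' PDB output delegates to [bio3d::write.pdb()]; mmCIF output writes a
#' minimal `atom_site` loop sufficient for round-tripping coordinates.
#'
#' @param structure A `gpcr_structure`.
#' @param path Output path.
#' @param dialect `"pdb"` or `"mmcif"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path,
                            dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif"
               else "pdb"
  het <- do.call(rbind, lapply(structure$het, `[[`, "atoms"))
  all_at <- rbind(structure$atom[, .atom_cols],
                  if (!is.null(het)) het[, .atom_cols])
  if (dialect == "pdb") {
    pdb <- bio3d::write.pdb(
      file = path, type = all_at$type, xyz = as.numeric(t(as.matrix(
        all_at[, c("x", "y", "z")]))), resno = all_at$resno,
      resid = all_at$resid, chain = all_at$chain, insert = all_at$insert,
      elety = all_at$elety, elesy = all_at$elesy, o = all_at$o)
  } else {
    .write_mmcif(all_at, structure$id, path)
  }
  invisible(path)
}

.atom_cols <- c("type", "elety", "resid", "chain", "resno", "insert",
                "x", "y", "z", "o", "elesy")

.write_mmcif <- function(at, id, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("data_", id), "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.label_entity_id",
               "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y",
               "_atom_site.Cartn_z", "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv",
               "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
               "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
               "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  ins <- ifelse(is.na(at$insert) | at$insert == "", "?", at$insert)
  writeLines(sprintf(
    "%-6s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
    at$type, seq_len(nrow(at)), at$elesy, at$elety, at$resid, at$chain,
    at$resno, ins, at$x, at$y, at$z, at$o, at$resno, at$resid, at$chain,
    at$elety), con)
  writeLines("#", con)
}
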