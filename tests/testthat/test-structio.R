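# Structural I/O: parsing, chain selection, ligand extraction,
# superposition, BW tables.

test_that("a minimal PDB parses into chains, residues and atoms", {
  atoms <- data.frame(
    elety = c("N", "CA", "C", "CA", "CA"),
    resid = c("GLY", "GLY", "GLY", "ALA", "SER"),
    chain = "A", resno = c(1, 1, 1, 2, 3),
    x = c(0, 1, 2, 4, 8), y = 0, z = 0)
  s <- parse_structure(write_pdb_fixture(atoms))
  expect_s3_class(s, "gpcr_structure")
  expect_equal(unique(s$atom$chain), "A")
  expect_equal(residue_keys(s), c("A:1", "A:2", "A:3"))
  expect_length(s$het, 0)
  expect_equal(chain_sequence(s, "A"), "GAS")
})

test_that("altloc resolution keeps the highest-occupancy copy", {
  atoms <- data.frame(
    elety = c("CA", "CA", "CA"),
    resid = "ALA", chain = "A", resno = c(1, 1, 2),
    alt = c("A", "B", ""),
    x = c(1, 9, 5), y = 0, z = 0, occ = c(0.4, 0.6, 1))
  s <- parse_structure(write_pdb_fixture(atoms))
  ca <- s$atom[s$atom$resno == 1, ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 9)  # the 0.6-occupancy altloc B copy

  # tie -> altloc A
  atoms$occ <- c(0.5, 0.5, 1)
  s2 <- parse_structure(write_pdb_fixture(atoms))
  expect_equal(s2$atom$x[s2$atom$resno == 1], 1)
})

test_that("water-only files raise the no-polymer error", {
  atoms <- data.frame(type = "HETATM", elety = "O", resid = "HOH",
                      chain = "A", resno = 1, x = 0, y = 0, z = 0,
                      elesy = "O")
  expect_error(parse_structure(write_pdb_fixture(atoms)), "no polymer")
  expect_error(parse_structure(tempfile()), "cannot read")
})

test_that("Smith-Waterman matches a brute-force DP oracle", {
  blosum <- gpcrmoa:::.load_blosum62()
  aln <- smith_waterman("HEAGAWGHEE", "PAWHEAE")
  expect_equal(aln$score, sw_oracle("HEAGAWGHEE", "PAWHEAE", blosum))
  set.seed(11)
  aa <- rownames(blosum)[1:20]
  for (i in 1:8) {
    q <- paste(sample(aa, sample(5:30, 1), replace = TRUE), collapse = "")
    t <- paste(sample(aa, sample(5:30, 1), replace = TRUE), collapse = "")
    expect_equal(smith_waterman(q, t)$score, sw_oracle(q, t, blosum),
                 info = paste(q, t))
  }
})

test_that("aligned pairs are strictly increasing in both coordinates", {
  aln <- smith_waterman("MKTAYIAKQRQISFVKSHFSRQLEERLGLIE",
                        "MKTAYIAKQRQISFVKSHFSRQ")
  p <- aln$aligned_pairs
  expect_true(all(diff(p[, 1]) > 0))
  expect_true(all(diff(p[, 2]) > 0))
  expect_gte(aln$identity_fraction, 0.9)
})

test_that("receptor chain selection picks the best-scoring chain", {
  ref <- "GASGAS"
  atoms <- rbind(
    data.frame(elety = "CA", resid = c("GLY", "ALA", "SER", "GLY", "ALA",
                                       "SER"),
               chain = "A", resno = 1:6, x = 1:6, y = 0, z = 0),
    data.frame(elety = "CA", resid = c("TRP", "TRP", "TRP", "TRP"),
               chain = "B", resno = 1:4, x = 1:4, y = 5, z = 0))
  s <- parse_structure(write_pdb_fixture(atoms))
  sel <- select_receptor_chain(s, ref)
  expect_equal(sel$chain_id, "A")
  expect_error(select_receptor_chain(
    parse_structure(write_pdb_fixture(
      data.frame(elety = "CA", resid = "TRP", chain = "A", resno = 1:4,
                 x = 1:4, y = 0, z = 0))), "GASGAS"),
    "no matching receptor chain")
})

test_that("ligand extraction applies the exclusion list and heavy-atom floor", {
  het <- function(resid, n, resno, chain = "X") data.frame(
    type = "HETATM", elety = paste0("C", seq_len(n)), resid = resid,
    chain = chain, resno = resno,
    x = seq_len(n), y = resno, z = 0, elesy = "C")
  atoms <- rbind(
    data.frame(type = "ATOM", elety = "CA", resid = "ALA", chain = "A",
               resno = 1, x = 0, y = 0, z = 0, elesy = "C"),
    het("HOH", 1, 101), het("LG1", 20, 102), het("GOL", 6, 103),
    het("NA", 1, 104), het("LG2", 8, 105))
  s <- parse_structure(write_pdb_fixture(atoms))
  ligs <- extract_ligands(s)
  expect_equal(vapply(ligs, `[[`, character(1), "comp_id"),
               c("LG1", "LG2"))  # waters, buffers, ions dropped; order kept
  expect_length(extract_ligands(s, exclude = c("LG1", "LG2",
                                               gpcrmoa:::.het_exclude_default)),
                0)
})

test_that("superpose recovers an exact rigid transform", {
  rec <- fixture_receptor()
  rot <- rot_z(0.9); tr <- c(3, -2, 7)
  mob <- transform_structure(rec$apo, rot, tr)
  fit <- superpose(mob, rec$apo)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$rotation %*% rot, diag(3), tolerance = 1e-8)
  expect_error(superpose(mob, rec$apo, selection = c("A:1", "A:2")),
               "insufficient correspondence")
})

test_that("superpose rmsd tracks the planted noise level", {
  rec <- fixture_receptor()
  keys <- residue_keys(rec$apo)[1:50]
  rmsds <- vapply(1:20, function(s) {
    set.seed(s)
    mob <- rec$apo
    sel <- mob$atom$elety == "CA" &
      gpcrmoa:::.atom_res_key(mob$atom) %in% keys
    mob$atom$x[sel] <- mob$atom$x[sel] + rnorm(sum(sel), sd = 0.1)
    mob$atom$y[sel] <- mob$atom$y[sel] + rnorm(sum(sel), sd = 0.1)
    mob$atom$z[sel] <- mob$atom$z[sel] + rnorm(sum(sel), sd = 0.1)
    superpose(mob, rec$apo, selection = keys)$rmsd
  }, numeric(1))
  expect_true(all(rmsds > 0.05 & rmsds < 0.2))
})

test_that("superpose is involution-consistent", {
  rec <- fixture_receptor()
  mob <- transform_structure(rec$apo, rot_z(1.2), c(1, 2, 3))
  fit <- superpose(mob, rec$apo)
  moved <- transform_structure(mob, fit$rotation, fit$translation)
  refit <- superpose(moved, rec$apo)
  expect_lt(abs(refit$rmsd - fit$rmsd), 1e-8)
})

test_that("BW tables load, reject duplicates, and skip absent residues", {
  rec <- fixture_receptor()
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chain_id\tauth_seq_id\tbw_number",
               "A\t61\t3.31", "A\t62\t3.32", "A\t63\t3.33"), tsv)
  bm <- load_bw_map(tsv, rec$apo)
  expect_equal(nrow(bm), 3L)
  expect_equal(bw_to_key(bm, "3.32"), "A:62")
  expect_equal(key_to_bw(bm, "A:63"), "3.33")

  writeLines(c("chain_id\tauth_seq_id\tbw_number",
               "A\t61\t3.50", "A\t62\t3.50"), tsv)
  expect_error(load_bw_map(tsv, rec$apo), "non-injective")

  writeLines(c("chain_id\tauth_seq_id\tbw_number",
               "A\t61\t3.31", "A\t9999\t3.32"), tsv)
  expect_warning(bm2 <- load_bw_map(tsv, rec$apo), "absent")
  expect_equal(nrow(bm2), 1L)
})

test_that("parse-write-parse round trips both dialects", {
  rec <- fixture_receptor()
  for (ext in c(".pdb", ".cif")) {
    f <- tempfile(fileext = ext)
    write_structure(rec$holo_inactive, f)
    back <- parse_structure(f)
    expect_equal(nrow(back$atom), nrow(rec$holo_inactive$atom))
    expect_equal(back$atom$elety, rec$holo_inactive$atom$elety)
    expect_equal(back$atom$x, rec$holo_inactive$atom$x, tolerance = 1e-3)
    expect_equal(back$atom$z, rec$holo_inactive$atom$z, tolerance = 1e-3)
    expect_length(back$het, 1L)
    expect_equal(nrow(back$het[[1]]$atoms),
                 nrow(rec$holo_inactive$het[[1]]$atoms))
  }
})
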