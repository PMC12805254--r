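# Shared fixtures, generated in code. The synthetic receptor ensemble is
# cached per session because several suites reuse it.

fixture_receptor <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_receptor()
    cache
  }
})

fixture_sites <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    rec <- fixture_receptor()
    holos <- list(list(structure = rec$holo_active,
                       ligand = rec$holo_active$het[[1]]),
                  list(structure = rec$holo_inactive,
                       ligand = rec$holo_inactive$het[[1]]))
    cbs <- consensus_binding_site(holos, chain = "A")
    cas <- consensus_allosteric_site(
      rec$apo, list(rec$holo_active, rec$holo_inactive),
      superpose_selection = stable_frame(rec))
    cache <<- list(cbs = cbs$cbs, cas = cas$cas,
                   cbs_prov = cbs$provenance, cas_prov = cas$provenance)
    cache
  }
})

fixture_graphs <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    rec <- fixture_receptor()
    sites <- fixture_sites()
    gp <- build_protein_graph(rec$apo, sites)
    cache <<- list(gp = gp, g_bs = cbs_subgraph(gp))
    cache
  }
})

stable_frame <- function(rec) {
  rp <- rec$spec$residues_per_helix
  stable_h <- setdiff(seq_len(rec$spec$n_helices), c(6L, 7L))
  paste0("A:", unlist(lapply(stable_h,
                             function(h) (h - 1L) * rp + seq_len(rp))))
}

# Minimal hand-written PDB fixture: `residues` is a data frame with
# chain, resno, resid and per-atom rows (elety, x, y, z, occ, alt).
write_pdb_fixture <- function(atoms, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$type %||% "ATOM", i, a$elety, a$alt %||% "", a$resid,
            a$chain, a$resno, a$x, a$y, a$z, a$occ %||% 1, 0,
            a$elesy %||% substr(a$elety, 1, 1))
  }, character(1L))
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force Smith-Waterman DP oracle under the same gap convention as
# the implementation (a gap of length L costs opening + L * extension).
sw_oracle <- function(query, target, blosum, open = 11, ext = 1) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  n <- length(q); m <- length(t)
  H <- matrix(0, n + 1, m + 1)  # best score ending at (i, j)
  Eg <- matrix(-Inf, n + 1, m + 1)  # gap in target (vertical)
  Fg <- matrix(-Inf, n + 1, m + 1)  # gap in query (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Eg[i, j] <- max(H[i - 1, j] - open - ext, Eg[i - 1, j] - ext)
      Fg[i, j] <- max(H[i, j - 1] - open - ext, Fg[i, j - 1] - ext)
      sub <- H[i - 1, j - 1] + blosum[q[i - 1], t[j - 1]]
      H[i, j] <- max(0, sub, Eg[i, j], Fg[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

rot_z <- function(theta)
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3L, byrow = TRUE)

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3L))
  r <- qr.Q(qr_d)
  if (det(r) < 0) r[, 1L] <- -r[, 1L]
  r
}

transform_graph <- function(g, rot, tr) {
  g$coords <- sweep(g$coords %*% t(rot), 2L, tr, "+")
  g
}
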