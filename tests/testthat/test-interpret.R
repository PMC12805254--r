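# Attention-based interpretability: residue importance, motif grouping,
# binding-residue AUROC, the alanine mutation probe, coordinate drift.

fake_pred <- function(attn_layers, cross_lp = NULL) {
  structure(list(self_attention = attn_layers,
                 interaction = list(cross_attention =
                                      list(ligand_to_protein = cross_lp)),
                 final_coords = NULL),
            class = "prediction_output")
}

test_that("uniform attention gives tied percentiles by average rank", {
  gr <- fixture_graphs()
  n <- nrow(gr$gp$nodes)
  uni <- matrix(1 / n, n, n)
  rep1 <- residue_importance(list(fake_pred(list(list(uni, uni)))),
                             gr$gp)
  # atom mass aggregates per residue: residues with 2 nodes get double
  # mass, so only check that single-node residues tie
  n_nodes <- table(gr$gp$nodes$residue_key)
  singles <- rep1[rep1$residue_key %in% names(n_nodes)[n_nodes == 1], ]
  expect_equal(length(unique(round(singles$raw, 12))), 1L)
  expect_true(all(rep1$rank_percentile >= 0 & rep1$rank_percentile <= 1))
  expect_error(residue_importance(list(), gr$gp), "empty")
})

test_that("a node hogging attention mass tops the ranking", {
  gr <- fixture_graphs()
  n <- nrow(gr$gp$nodes)
  a <- matrix((1 - 0.9) / (n - 1), n, n)
  a[, 7] <- 0.9
  rep1 <- residue_importance(list(fake_pred(list(list(a)))), gr$gp)
  top_res <- gr$gp$nodes$residue_key[7]
  expect_equal(rep1$residue_key[which.max(rep1$rank_percentile)],
               top_res)
  expect_equal(max(rep1$rank_percentile),
               (nrow(rep1) - 0.5) / nrow(rep1))
})

test_that("importance is stable under rigid transforms of the input", {
  gr <- fixture_graphs()
  model <- init_model(model_config(hidden_dim = 16, attention_heads = 2,
                                   egnn_layers_encoder = 1,
                                   egnn_layers_propagation = 1,
                                   self_attention_layers = 1, seed = 3))
  gl <- build_ligand_graph("Oc1ccccc1")
  p1 <- forward_pass(model, gr$gp, gr$g_bs, gl)
  rot <- random_rotation()
  p2 <- forward_pass(model, transform_graph(gr$gp, rot, c(1, 1, 1)),
                     transform_graph(gr$g_bs, rot, c(1, 1, 1)),
                     transform_graph(gl, rot, c(1, 1, 1)))
  r1 <- residue_importance(list(p1), gr$gp)
  r2 <- residue_importance(list(p2), gr$gp)
  expect_equal(r1$raw, r2$raw, tolerance = 1e-6)
})

test_that("motif means average the member-residue percentiles", {
  rec <- fixture_receptor()
  gr <- fixture_graphs()
  n <- nrow(gr$gp$nodes)
  # plant high attention mass on the DRY residues (3.49/3.50/3.51)
  dry_keys <- bw_to_key(rec$bwmap, c("3.49", "3.50", "3.51"))
  cols <- which(gr$gp$nodes$residue_key %in% dry_keys)
  a <- matrix(0.1 / n, n, n)
  if (length(cols)) a[, cols] <- 2
  rep1 <- residue_importance(list(fake_pred(list(list(a)))), gr$gp)
  mm <- motif_importance(rep1, rec$bwmap)
  if ("DRY" %in% names(mm) && "PIF" %in% names(mm))
    expect_gt(mm[["DRY"]], mm[["PIF"]])
  # all-equal percentiles give equal motif means
  rep_flat <- rep1
  rep_flat$rank_percentile <- 0.5
  mf <- motif_importance(rep_flat, rec$bwmap)
  expect_true(all(abs(mf - mf[1]) < 1e-12))
  # a map without any CWxP residue omits the motif with a warning
  bm_small <- structure(
    data.frame(key = bw_to_key(rec$bwmap, c("3.49", "3.50", "3.51")),
               bw_number = c("3.49", "3.50", "3.51")),
    class = c("bw_map", "data.frame"))
  expect_warning(m2 <- motif_importance(rep1, bm_small), "CWxP")
  expect_false("CWxP" %in% names(m2))
})

test_that("AUROC agrees with the all-pairs oracle and wilcox.test", {
  set.seed(41)
  for (i in 1:5) {
    n <- 60
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE,
                     prob = c(0.3, 0.7))
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n) + labels * runif(1, 0, 2)
    scores[sample(n, 10)] <- round(scores[sample(n, 10)], 0)  # ties
    got <- auroc_mann_whitney(scores, labels)
    pos <- scores[labels]; neg <- scores[!labels]
    pairs <- outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(got, mean(pairs), tolerance = 1e-12)
    w <- suppressWarnings(wilcox.test(pos, neg))
    expect_equal(got, unname(w$statistic) / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
  expect_equal(auroc_mann_whitney(c(1, 1, 1, 1), c(TRUE, TRUE, FALSE,
                                                   FALSE)), 0.5)
  expect_equal(auroc_mann_whitney(c(3, 4, 1, 2),
                                  c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_error(auroc_mann_whitney(1:3, c(TRUE, TRUE, TRUE)),
               "both classes")
})

test_that("shuffled scores give chance-level AUROC", {
  set.seed(42)
  aurocs <- replicate(50, {
    labels <- rep(c(TRUE, FALSE), 500)
    auroc_mann_whitney(rnorm(1000), labels)
  })
  expect_lt(abs(mean(aurocs) - 0.5), 0.05)
})

test_that("cross-attention binding scores flow through to an AUROC", {
  gr <- fixture_graphs()
  model <- init_model(model_config(hidden_dim = 16, attention_heads = 2,
                                   egnn_layers_encoder = 1,
                                   egnn_layers_propagation = 1,
                                   self_attention_layers = 1, seed = 5))
  gl <- build_ligand_graph("Oc1ccccc1")
  p <- forward_pass(model, gr$gp, gr$g_bs, gl)
  sites <- fixture_sites()
  half <- sites$cbs[seq_len(ceiling(length(sites$cbs) / 2))]
  a <- binding_residue_auroc(p, half, gr$g_bs)
  expect_gte(a, 0); expect_lte(a, 1)
})

test_that("the alanine probe only changes the mutated residue", {
  rec <- fixture_receptor()
  sites <- fixture_sites()
  target <- bw_to_key(rec$bwmap, "3.50")
  mut <- rec$apo
  sel <- gpcrmoa:::.atom_res_key(mut$atom) == target
  mut$atom$resid[sel] <- "ALA"
  mut$atom <- mut$atom[!(sel & mut$atom$elety != "CA"), ]
  gp0 <- build_protein_graph(rec$apo, sites)
  gp1 <- build_protein_graph(mut, sites)
  same <- intersect(which(gp0$nodes$residue_key != target),
                    seq_len(nrow(gp1$nodes)))
  keep0 <- gp0$nodes$residue_key != target
  keep1 <- gp1$nodes$residue_key != target
  expect_identical(gp0$features[keep0, ], gp1$features[keep1, ])
})

test_that("mutating alanine to alanine is a no-op for the model", {
  rec <- fixture_receptor()
  sites <- fixture_sites()
  # pick an ALA residue inside the graph
  gp <- build_protein_graph(rec$apo, sites)
  ala <- gp$nodes$residue_key[gp$nodes$resid == "ALA"][1]
  skip_if(is.na(ala), "no alanine in the site union")
  model <- init_model(model_config(hidden_dim = 16, attention_heads = 2,
                                   egnn_layers_encoder = 1,
                                   egnn_layers_propagation = 1,
                                   self_attention_layers = 1, seed = 6))
  res <- mutate_and_rescore(model, rec$apo, sites, ala,
                            list(build_ligand_graph("Oc1ccccc1")))
  expect_equal(res$p_bind_before, res$p_bind_after, tolerance = 1e-12)
  expect_equal(res$p_agonist_before, res$p_agonist_after,
               tolerance = 1e-12)
  expect_error(mutate_and_rescore(model, rec$apo, sites, "A:9999",
                                  list()), "absent")
})

test_that("coordinate drift is zero against identical coordinates", {
  gr <- fixture_graphs()
  fake <- structure(list(final_coords = gr$gp$coords),
                    class = "prediction_output")
  d <- coordinate_drift(fake, gr$gp)
  expect_true(all(d$drift_rmsd < 1e-10))
  rec <- fixture_receptor()
  d2 <- coordinate_drift(fake, gr$gp, reference = rec$apo)
  expect_equal(d2$approach_rmsd, d2$drift_rmsd, tolerance = 1e-10)
})

test_that("importance reports export as two-column text", {
  gr <- fixture_graphs()
  n <- nrow(gr$gp$nodes)
  rep1 <- residue_importance(list(fake_pred(list(list(
    matrix(1 / n, n, n))))), gr$gp)
  f <- tempfile()
  write_residue_scores(rep1, f)
  back <- read.table(f, sep = "\t")
  expect_equal(nrow(back), nrow(rep1))
})
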