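# Activation-geometry metrics, displacement profiles, allosteric-site
# counting, Welch test and the axis-aligned split probe.

make_anchor_structure <- function(anchors) {
  # anchors: named list bw -> c(x, y, z); builds a one-chain CA trace and
  # matching BW map
  keys <- names(anchors)
  atoms <- do.call(rbind, lapply(seq_along(anchors), function(i)
    data.frame(elety = "CA", resid = "ALA", chain = "A", resno = i,
               x = anchors[[i]][1], y = anchors[[i]][2],
               z = anchors[[i]][3])))
  s <- parse_structure(write_pdb_fixture(atoms))
  bm <- structure(data.frame(key = paste0("A:", seq_along(anchors)),
                             bw_number = keys, stringsAsFactors = FALSE),
                  class = c("bw_map", "data.frame"))
  list(s = s, bm = bm)
}

test_that("TM6 metric equals the hand-computed centroid distance", {
  f <- make_anchor_structure(list(
    "3.50" = c(0, 0, 0), "6.30" = c(13, 0, 0), "6.34" = c(13, 1, 0),
    "6.48" = c(13, -1, 0)))
  m <- activation_metrics(f$s, f$bm)
  expect_equal(m$dist_tm6, 13)
  expect_true(is.na(m$dist_tm7))  # no TM7 anchors present
  expect_equal(m$residues_used$tm6, c("6.30", "6.34", "6.48"))
})

test_that("a missing anchor falls back to the two-residue centroid", {
  f <- make_anchor_structure(list(
    "3.50" = c(0, 0, 0), "6.30" = c(13, 2, 0), "6.34" = c(13, -2, 0)))
  m <- activation_metrics(f$s, f$bm)
  expect_equal(m$dist_tm6, 13)  # mean of the two anchors is (13, 0, 0)
  f1 <- make_anchor_structure(list("3.50" = c(0, 0, 0),
                                   "6.30" = c(13, 0, 0)))
  expect_true(is.na(activation_metrics(f1$s, f1$bm)$dist_tm6))
})

test_that("a BW map without R3.50 is an error", {
  f <- make_anchor_structure(list("6.30" = c(13, 0, 0),
                                  "6.34" = c(13, 1, 0)))
  expect_error(activation_metrics(f$s, f$bm), "reference residue missing")
})

test_that("activation metrics are invariant under rigid transforms", {
  rec <- fixture_receptor()
  m0 <- activation_metrics(rec$apo, rec$bwmap)
  m1 <- activation_metrics(
    transform_structure(rec$apo, random_rotation(), c(11, -4, 2)),
    rec$bwmap)
  expect_equal(m1$dist_tm6, m0$dist_tm6, tolerance = 1e-10)
  expect_equal(m1$dist_tm7, m0$dist_tm7, tolerance = 1e-10)
})

test_that("displacement profile is zero for identical states and after rigid motion", {
  rec <- fixture_receptor()
  p0 <- displacement_profile(rec$apo, rec$apo)
  expect_true(all(p0$ca < 1e-10))
  rot <- transform_structure(rec$apo, rot_z(0.5), c(2, 2, 2))
  p1 <- displacement_profile(rec$apo, rot)
  expect_true(all(p1$ca < 1e-6))
})

test_that("a planted single-residue shift is recovered after fitting on the rest", {
  rec <- fixture_receptor()
  holo <- rec$apo
  sel <- gpcrmoa:::.atom_res_key(holo$atom) == "A:10"
  holo$atom$x[sel] <- holo$atom$x[sel] + 4.2
  others <- setdiff(residue_keys(rec$apo), "A:10")
  p <- displacement_profile(rec$apo, holo, superpose_selection = others)
  expect_equal(unname(p$ca["A:10"]), 4.2, tolerance = 0.01)
  expect_lt(max(p$ca[names(p$ca) != "A:10"]), 0.05)
})

test_that("allosteric site counts strict >4 A movers outside the binding site", {
  rec <- fixture_receptor()
  holo <- rec$apo
  movers <- paste0("A:", 1:5)
  for (k in movers) {
    sel <- gpcrmoa:::.atom_res_key(holo$atom) == k
    holo$atom$y[sel] <- holo$atom$y[sel] + 5
  }
  frame <- paste0("A:", 31:210)
  as1 <- allosteric_site(rec$apo, list(holo), cbs = movers[1:2],
                         superpose_selection = frame)
  expect_equal(as1$count, 3L)
  expect_setequal(as1$as_residues, movers[3:5])
  expect_false(as1$complex_flag)
  # no mover above threshold
  as0 <- allosteric_site(rec$apo, list(rec$apo), cbs = character())
  expect_equal(as0$count, 0L)
  expect_false(as0$complex_flag)
})

test_that("a 201-mover receptor is flagged allosterically complex", {
  rec <- fixture_receptor()
  holo <- rec$apo
  movers <- paste0("A:", 1:201)
  sel <- gpcrmoa:::.atom_res_key(holo$atom) %in% movers
  holo$atom$y[sel] <- holo$atom$y[sel] + 5
  as1 <- allosteric_site(rec$apo, list(holo), cbs = character(),
                         superpose_selection = paste0("A:", 202:210))
  expect_equal(as1$count, 201L)
  expect_true(as1$complex_flag)
})

test_that("welch_t matches stats::t.test and handles degenerate input", {
  a <- c(1.2, 2.4, 3.1, 4.8, 2.2); b <- c(5.1, 6.7, 5.9, 8.2)
  w <- welch_t(a, b)
  ref <- t.test(a, b)
  expect_equal(w$t, unname(ref$statistic))
  expect_equal(w$df, unname(ref$parameter))
  expect_equal(w$p_two_sided, ref$p.value)

  same <- welch_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p_two_sided, 1)
  expect_lt(welch_t(c(1, 2, 3, 4), c(11, 12, 13, 14))$p_two_sided, 1e-4)
  expect_equal(welch_t(c(2, 2, 2), c(2, 2))$p_two_sided, 1)
  expect_equal(welch_t(c(2, 2, 2), c(3, 3))$p_two_sided, 0)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("best_axis_split separates a trivially separable 1-D table", {
  tab <- data.frame(f = c(1, 2, 9, 10),
                    label = c("A", "A", "B", "B"))
  s <- best_axis_split(tab)
  expect_equal(s$feature_name, "f")
  expect_equal(s$threshold, 5.5)
  expect_equal(s$gini_gain, 0.5)
  expect_equal(s$fraction_separated, 1.0)
  expect_error(best_axis_split(data.frame(f = 1:3, label = "A")),
               "degenerate labels")
  flat <- best_axis_split(data.frame(f = rep(1, 4),
                                     label = c("A", "A", "B", "B")))
  expect_equal(flat$gini_gain, 0)
})

test_that("best_axis_split agrees with a brute-force oracle", {
  oracle <- function(tab) {
    y <- tab$label
    gini <- function(v) { p <- mean(v == y[1]); 1 - p^2 - (1 - p)^2 }
    best <- list(gain = -1)
    for (f in sort(setdiff(names(tab), "label"))) {
      v <- tab[[f]]
      for (thr in sort(unique(v))[-1] - diff(sort(unique(v))) / 2) {
        l <- v <= thr
        gain <- gini(y) - mean(l) * gini(y[l]) - mean(!l) * gini(y[!l])
        if (gain > best$gain + 1e-12)
          best <- list(f = f, thr = thr, gain = gain)
      }
    }
    best
  }
  set.seed(21)
  for (rep in 1:6) {
    n <- sample(10:50, 1)
    tab <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                      label = sample(c("x", "y"), n, replace = TRUE))
    if (length(unique(tab$label)) < 2) next
    got <- best_axis_split(tab)
    ref <- oracle(tab)
    expect_equal(got$gini_gain, ref$gain, tolerance = 1e-10)
    expect_equal(got$feature_name, ref$f)
    expect_equal(got$threshold, ref$thr, tolerance = 1e-10)
  }
})

test_that("best_axis_split recovers a planted threshold among noise columns", {
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    n <- 200
    lab <- sample(c("agonist_bound", "antagonist_bound"), n, replace = TRUE)
    planted <- ifelse(lab == "agonist_bound",
                      13.2 + abs(rnorm(n, 1.5, 0.8)),
                      13.2 - abs(rnorm(n, 1.5, 0.8)))
    tab <- data.frame(Dist_planted = planted,
                      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                      n4 = rnorm(n), n5 = rnorm(n), label = lab)
    s <- best_axis_split(tab)
    if (s$feature_name == "Dist_planted" &&
        s$threshold >= 13.0 && s$threshold <= 13.4)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("geometry feature tables carry distances, displacements and labels", {
  rec <- fixture_receptor()
  tab <- geometry_feature_table(
    list(rec$holo_inactive, rec$holo_active),
    labels = c("antagonist_bound", "agonist_bound"),
    bwmaps = rec$bwmap,
    dist_pairs = rbind(c("3.50", "6.30"), c("3.50", "7.53")),
    apo = rec$apo, superpose_selection = stable_frame(rec))
  expect_true(all(c("Dist_3.50_6.30", "Dist_3.50_7.53", "label") %in%
                    names(tab)))
  expect_gt(tab$Dist_3.50_6.30[2], tab$Dist_3.50_6.30[1])  # TM6 opens
  expect_false(anyDuplicated(names(tab)) > 0)
  f <- tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  expect_equal(read_feature_table(f)$label, tab$label)
})
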