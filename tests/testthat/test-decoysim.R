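test_that("make_native is deterministic and satisfies contact/clash constraints", {
  a <- make_native(12, 10, seed = 71)
  b <- make_native(12, 10, seed = 71)
  expect_identical(a, b)
  expect_false(identical(ca_coords(make_native(12, 10, seed = 72)), ca_coords(a)))
  q <- quality_report(a, a)
  expect_equal(q$fnat, 1)
  expect_equal(q$capri_class, "high")
  for (seed in 81:95) {
    nat <- make_native(10, 9, seed = seed)
    expect_gte(length(oracle_contacts(nat)), 5L)
    d <- oracle_dist_matrix(ca_coords(nat, "a"), ca_coords(nat, "b"))
    expect_gte(min(d), 3.5)
    # consecutive CA spacing close to ideal
    ca <- ca_coords(nat, "a")
    steps <- sqrt(rowSums(diff(ca)^2))
    expect_true(all(abs(steps - 3.8) < 0.8))
  }
})

test_that("decoy ladder spans quality classes with graded medians", {
  cfg <- sim_config(n_natives = 3, decoys_per_native = 20, seed = 73)
  labs <- do.call(rbind, lapply(1:10, function(k) {
    nat <- make_native(16, 12, seed = 400 + k)
    recs <- make_decoys(nat, cfg, seed = 500 + k)
    do.call(rbind, lapply(recs, function(r)
      cbind(r$quality, rot = r$noise_level[1], tr = r$noise_level[2])))
  }))
  # zero-noise rung reproduces the native exactly
  zero <- labs[labs$rot == 0 & labs$tr == 0, ]
  expect_true(all(zero$dockq > 1 - 1e-9))
  expect_true(all(zero$binary_label == 1))
  # largest rung is always incorrect
  worst <- labs[labs$rot == 180, ]
  expect_true(all(worst$capri_class == "incorrect"))
  expect_true(all(worst$binary_label == 0))
  # medians strictly decrease along the ladder
  meds <- sapply(split(labs$dockq, interaction(labs$rot, labs$tr, drop = TRUE)),
                 stats::median)
  ord <- c("0.0", "5.1", "15.4", "60.15", "180.60")
  expect_true(all(diff(meds[ord]) < 0))
})

test_that("stored labels equal quality recomputed from scratch", {
  ds <- simulate_dataset(sim_config(n_natives = 3, decoys_per_native = 5, seed = 74,
                                    split_fractions = c(0.4, 0.3, 0.3)))
  for (r in ds$records) {
    nat <- ds$natives[[which(vapply(ds$natives, `[[`, "", "source_id") == r$native_id)]]
    q <- quality_report(r$decoy, nat)
    expect_equal(q, r$quality, tolerance = 1e-12)
  }
})

test_that("synthetic embeddings are deterministic, type-keyed, and alignable", {
  nat <- make_native(12, 10, seed = 75)
  e1 <- synthetic_embeddings(nat, dim = 8, seed = 3)
  e2 <- synthetic_embeddings(nat, dim = 8, seed = 3)
  expect_identical(e1, e2)
  # two residues of the same type at different positions differ only by the
  # deterministic positional component
  aa <- nat$partner_a$aa_type
  dup <- which(duplicated(aa) | duplicated(aa, fromLast = TRUE))
  if (length(dup) >= 2) {
    i <- dup[1]; j <- dup[which(aa[dup] == aa[i])[2]]
    ec <- as.matrix(e1[, -(1:2)])
    jitter_i <- 0.05 * sin(0.37 * i * seq_len(8))
    jitter_j <- 0.05 * sin(0.37 * j * seq_len(8))
    expect_equal(ec[i, ] - jitter_i, ec[j, ] - jitter_j,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # integration: every generated complex aligns with its own sidecar
  for (seed in 1:10) {
    nat <- make_native(9, 8, seed = 600 + seed)
    emb <- synthetic_embeddings(nat, dim = 4, seed = 1)
    expect_silent(build_graph(nat, graph_config(embedding_dim = 4), embeddings = emb))
  }
})

test_that("group-wise splits have the right sizes and zero native leakage", {
  cfg <- sim_config(n_natives = 20, decoys_per_native = 2, seed = 76,
                    chain_lengths = c(8, 8))
  ds <- simulate_dataset(cfg)
  tab <- table(unique(ds$labels[, c("native_id", "split")])$split)
  expect_equal(as.integer(tab[c("train", "val", "test")]), c(14L, 3L, 3L))
  leak <- tapply(ds$labels$split, ds$labels$native_id,
                 function(s) length(unique(s)))
  expect_true(all(leak == 1))
  sp1 <- split_dataset(ds$records, cfg)
  sp2 <- split_dataset(ds$records, cfg)
  expect_identical(sp1, sp2)
  expect_error(split_dataset(ds$records[1:2], cfg), "sizing")
})

test_that("split fractions approach 70/15/15 as the native count grows", {
  recs <- lapply(seq_len(100), function(k)
    list(native_id = sprintf("n%03d", k)))
  sp <- split_dataset(recs, sim_config(n_natives = 100, seed = 9))
  fr <- table(sp$natives) / 100
  expect_lte(abs(fr[["train"]] - 0.70), 1 / 100)
  expect_lte(abs(fr[["val"]] - 0.15), 1 / 100)
  expect_lte(abs(fr[["test"]] - 0.15), 1 / 100)
})

test_that("AFM sidecar values are in range and the target follows its formula", {
  ds <- simulate_dataset(sim_config(n_natives = 3, decoys_per_native = 5, seed = 77,
                                    split_fractions = c(0.4, 0.3, 0.3)),
                         with_afm = TRUE)
  expect_true(all(ds$labels$iptm >= 0 & ds$labels$iptm <= 1))
  expect_true(all(ds$labels$ptm >= 0 & ds$labels$ptm <= 1))
  expect_equal(ds$labels$afm_target,
               0.8 * ds$labels$iptm + 0.2 * ds$labels$ptm + ds$labels$dockq)
  expect_gt(stats::cor(ds$labels$iptm, ds$labels$dockq, method = "spearman"), 0.5)
})
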