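test_that("intermolecular pairs use a strict cutoff", {
  a <- matrix(c(0, 0, 0), 1)
  expect_equal(nrow(intermolecular_pairs(a, matrix(c(4.9, 0, 0), 1), 5)), 1)
  expect_equal(nrow(intermolecular_pairs(a, matrix(c(5.1, 0, 0), 1), 5)), 0)
  expect_equal(nrow(intermolecular_pairs(a, matrix(c(5.0, 0, 0), 1), 5)), 0)
})

test_that("pair search equals the brute-force double loop on a 100-atom pose", {
  pa <- random_conformation(10, 1) * 2
  pb <- sweep(random_conformation(10, 2) * 2, 2, c(3, 1, -2), "+")
  got <- intermolecular_pairs(pa, pb, 5)
  ref <- NULL
  for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb)))
    if (sqrt(sum((pa[i, ] - pb[j, ])^2)) < 5) ref <- rbind(ref, c(i, j))
  expect_identical(path_set(got), path_set(ref))
  expect_gt(nrow(got), 0)
})

test_that("merging preserves both bonded graphs and types the crossing edges", {
  protein <- make_record(rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.3, 1.3, 0),
                               c(3.8, 1.3, 0.6), c(4.6, 2.6, 0.2)),
                         rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)),
                         mol_id = "prot", feat_seed = 1)
  ligand <- make_record(rbind(c(0, 3, 0), c(1.5, 3, 0), c(3, 30, 0)),
                        rbind(c(1, 2), c(2, 3)), mol_id = "lig",
                        feat_seed = 2)
  cx <- merge_complex(protein, ligand, cutoff = 5)
  expect_equal(cx$record$n_atoms, 8L)
  # every nonbonded edge crosses the boundary, within the cutoff
  nb <- cx$nonbonded_pairs
  expect_gt(nrow(nb), 0)
  crosses <- xor(nb[, 1] <= 5, nb[, 2] <= 5)
  expect_true(all(crosses))
  d <- path_distances(cx$record$positions, nb)
  expect_true(all(d < 5))
  # no bonded edge crosses the boundary
  b <- cx$record$bonds
  expect_true(all((b[, 1] <= 5) == (b[, 2] <= 5)))
  # separation property: dropping nonbonded edges recovers the disjoint union
  expect_identical(path_set(cx$record$bonds),
                   path_set(rbind(protein$bonds, ligand$bonds + 5L)))
  # hop-1 size of the prepared input: 2 x bonds + directed nonbonded edges
  cfg <- tiny_config(complex_mode = TRUE)
  prep <- ffinet:::prepare_complex(cx, cfg)
  expect_equal(nrow(prep$paths[[1]]), 2 * nrow(cx$record$bonds) + nrow(nb))

  # degenerate cutoff and far translation give a disjoint union
  expect_error(merge_complex(protein, ligand, cutoff = 0))
  far <- ligand
  far$positions <- far$positions + 100
  expect_equal(nrow(merge_complex(protein, far, cutoff = 5)$nonbonded_pairs), 0)
})

test_that("nonbonded edge count is nondecreasing in the cutoff", {
  pa <- random_conformation(8, 11) * 1.5
  pb <- sweep(random_conformation(8, 12) * 1.5, 2, c(2, 0, 0), "+")
  counts <- vapply(c(1, 2, 3, 5, 8, 12),
                   function(ct) nrow(intermolecular_pairs(pa, pb, ct)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("no multi-hop chain traverses a nonbonded edge", {
  protein <- make_record(rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0)),
                         rbind(c(1, 2), c(2, 3)), feat_seed = 3)
  ligand <- make_record(rbind(c(0, 2, 0), c(1.5, 2, 0), c(3, 2, 0)),
                        rbind(c(1, 2), c(2, 3)), feat_seed = 4)
  cx <- merge_complex(protein, ligand, cutoff = 5)
  cfg <- tiny_config(complex_mode = TRUE)
  prep <- ffinet:::prepare_complex(cx, cfg)
  bonded <- path_set(rbind(cx$record$bonds, cx$record$bonds[, 2:1]))
  for (k in 2:3) {
    p <- prep$paths[[k]]
    for (r in seq_len(k)) {
      steps <- path_set(p[, c(r, r + 1), drop = FALSE])
      expect_true(all(steps %in% bonded))
    }
  }
  # nonbonded hop-1 rows carry the nonbonded basis, bonded rows the bond basis
  n_b <- 2 * nrow(cx$record$bonds)
  expect_true(all(prep$basis[[1]][seq_len(n_b), 1] > 0))
  expect_true(all(prep$basis[[1]][-seq_len(n_b), ] == 0))
  expect_true(all(prep$basis1_nb[seq_len(n_b), ] == 0))
  expect_true(all(prep$basis1_nb[-seq_len(n_b), 1] > 0))
})

test_that("pocket pruning keeps near atoms and re-indexes bonds", {
  protein <- make_record(rbind(c(0, 0, 0), c(1.5, 0, 0), c(30, 0, 0),
                               c(31.5, 0, 0)),
                         rbind(c(1, 2), c(3, 4)), feat_seed = 5)
  ligand <- make_record(matrix(c(0, 2, 0), 1), NULL, feat_seed = 6)
  cx <- merge_complex(protein, ligand, cutoff = 5, pocket_radius = 10)
  expect_equal(cx$n_protein, 2L)
  expect_identical(path_set(cx$record$bonds[1, , drop = FALSE]), "1-2")
})

test_that("a complex-mode model trains end-to-end on synthetic poses", {
  cxs <- lapply(1:12, function(i) make_synthetic_complex(seed = i))
  labels <- vapply(cxs, `[[`, numeric(1), "affinity")
  expect_true(all(is.finite(labels)))
  cfg <- tiny_config(complex_mode = TRUE, n_layers = 1)
  split <- list(train = 1:8, val = 9:10, test = 11:12)
  fit <- fit_ffinet(ffinet_model(cfg), cxs, split = split,
                    train_config = ffinet_train_config(batch_size = 4,
                                                       max_epochs = 3,
                                                       seed = 1))
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_equal(dim(predict(fit$model, cxs[11:12])), c(2L, 1L))
})

test_that("PDBBind-style layout loads", {
  root <- tempfile("pdbbind")
  id <- "1abc"
  dir.create(file.path(root, id), recursive = TRUE)
  lig <- fixture_molecules()$ethanol
  write_sdf(lig, file.path(root, id, paste0(id, "_ligand.sdf")))
  pos <- sweep(lig$positions, 2, c(4, 0, 0), "+")
  writeLines(c(
    sprintf("ATOM  %5d  C   POC A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, pos[, 1] + c(0, 1.5, 3.0), pos[, 2], pos[, 3]),
    "END"), file.path(root, id, paste0(id, "_pocket.pdb")))
  writeLines(c("# header", paste(id, "6.42")), file.path(root, "index.txt"))
  idx <- read_pdbbind_index(file.path(root, "index.txt"))
  expect_equal(idx$id, id)
  expect_equal(idx$affinity, 6.42)
  suppressWarnings(cx <- load_pdbbind_complex(root, id, affinity = idx$affinity))
  expect_s3_class(cx, "ffinet_complex")
  expect_equal(cx$affinity, 6.42)
  expect_equal(cx$n_ligand, 3L)
})
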