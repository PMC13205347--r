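# Synthetic data: molecule sampler, chemical-shift model, renderer and the
# pair/manifest builder.

test_that("sampled molecules always satisfy the composition constraints", {
  set.seed(50)
  for (k in 1:1000) {
    g <- sample_molecule(c(1L, 16L))
    v <- validate_molecule(g)
    expect_true(v$ok)
    # valence caps: bond-order sum never exceeds the element's valence
    vs <- integer(g$heavy_atom_count)
    b <- g$bond_orders
    for (r in seq_len(nrow(b))) {
      vs[b$i[r]] <- vs[b$i[r]] + b$order[r]
      vs[b$j[r]] <- vs[b$j[r]] + b$order[r]
    }
    cap <- c(C = 4L, N = 3L, O = 2L)[g$atom_elements]
    expect_true(all(vs <= cap))
  }
})

test_that("the sampler is reproducible under a fixed seed", {
  draw <- function() {
    set.seed(99)
    replicate(25, sample_molecule(c(2L, 16L)), simplify = FALSE)
  }
  a <- draw(); b <- draw()
  expect_identical(lapply(a, `[[`, "node_features"), lapply(b, `[[`, "node_features"))
  expect_identical(lapply(a, `[[`, "edges"), lapply(b, `[[`, "edges"))
  expect_error(sample_molecule(c(0L, 20L)), "size_range")
})

test_that("chemical shifts are deterministic, in range, and base-anchored", {
  # single carbon: the 13C shift is the sp3 base value; one 1H group, weight 4
  g <- smiles_to_graph("C")
  tab <- assign_chemical_shifts(g)
  model <- default_shift_model()
  expect_equal(nrow(tab$c13), 1L)
  expect_equal(tab$c13$shift_ppm,
               unname(model$c13_base["C_sp3"]) +
                 (nmrmatch:::atom_env_ids(g) %% 1000 / 1000 - 0.5) * 2 * model$c13_jitter)
  expect_equal(tab$h1$weight, 4L)
  # determinism for identical canonical structures
  t1 <- assign_chemical_shifts(smiles_to_graph("OCC"))
  t2 <- assign_chemical_shifts(smiles_to_graph(canonical_smiles("CCO")))
  expect_equal(sort(t1$c13$shift_ppm), sort(t2$c13$shift_ppm))
  # ranges over many random molecules
  set.seed(51)
  for (k in 1:1000) {
    tab <- assign_chemical_shifts(sample_molecule(c(1L, 16L)))
    expect_true(all(tab$h1$shift_ppm >= 2 & tab$h1$shift_ppm <= 12.05))
    if (nrow(tab$c13))
      expect_true(all(tab$c13$shift_ppm >= 2 & tab$c13$shift_ppm <= 230))
  }
})

test_that("rendered spectra have the contracted geometry", {
  g <- smiles_to_graph("CCO")
  tab <- assign_chemical_shifts(g)
  img <- render_spectrum_image(tab, render_spec("1H", seed = 1))
  expect_equal(dim(img), c(256L, 256L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  # empty peak list, zero noise and drift: constant background
  empty <- list(c13 = data.frame(atom = integer(), shift_ppm = numeric()),
                h1 = data.frame(atom = integer(), shift_ppm = numeric(),
                                weight = integer()))
  flat <- render_spectrum_image(empty, render_spec("13C", noise_sd = 0,
                                                   drift_amplitude = 0, seed = 1))
  expect_equal(length(unique(as.vector(flat))), 1L)
})

test_that("a single peak lands at its affine ppm-to-pixel column", {
  for (p in c(3, 5.5, 9.8, 12)) {
    tab <- list(c13 = data.frame(atom = integer(), shift_ppm = numeric()),
                h1 = data.frame(atom = 1L, shift_ppm = p, weight = 2L))
    spec <- render_spec("1H", noise_sd = 0, drift_amplitude = 0, seed = 1)
    prof <- render_profile(tab, spec)
    expect_lte(abs(which.max(prof) - ppm_to_pixel(p, spec)), 1L)
  }
  spec13 <- render_spec("13C")
  expect_equal(ppm_to_pixel(230, spec13), 1L)   # high ppm at the left edge
  expect_equal(ppm_to_pixel(2, spec13), 256L)   # low ppm at the right edge
  expect_true(all(diff(ppm_to_pixel(seq(230, 2, length.out = 50), spec13)) >= 0))
})

test_that("pair manifests have the contracted arithmetic", {
  # 2 spectrum records per molecule and 1:1 positives/negatives per split
  mols <- nmrmatch:::enumerate_molecules(30)
  man <- suppressWarnings(build_pair_dataset(mols, seed = 1))
  expect_equal(nrow(man$spectra), 60L)
  tab <- table(man$pairs$split, man$pairs$label)
  expect_true(all(tab[, "0"] == tab[, "1"]))
  # minimum viable input: 5 molecules give 10 spectrum records, 5 pos, 5 neg
  # per negative mode over the whole set
  man5 <- suppressWarnings(build_pair_dataset(nmrmatch:::enumerate_molecules(5), seed = 1))
  expect_equal(nrow(man5$spectra), 10L)
  core <- man5$pairs[man5$pairs$split %in% c("train", "val", "test_rand"), ]
  expect_equal(sum(core$label == 1L), 5L)
  expect_equal(sum(core$label == 0L), 5L)
})

test_that("manifest invariants hold across a 10-seed sweep", {
  mols <- nmrmatch:::enumerate_molecules(40)
  graphs <- lapply(mols$smiles, nmrmatch:::chain_graph)
  for (seed in 1:10) {
    man <- suppressWarnings(build_pair_dataset(mols, graphs = graphs, seed = seed))
    p <- man$pairs
    # 1:1 within every split
    tab <- table(p$split, p$label)
    expect_true(all(tab[, "0"] == tab[, "1"]))
    # molecule-level split disjointness
    sp <- man$splits
    expect_equal(anyDuplicated(sp$id), 0L)
    expect_setequal(unique(p$split), c("train", "val", "test_rand", "test_diff"))
    # a molecule's positive pairs stay in its own split
    pos <- p[p$label == 1L, ]
    pos$base <- ifelse(pos$split %in% c("test_rand", "test_diff"), "test", pos$split)
    expect_true(all(pos$base == sp$split[match(pos$mol_id, sp$id)]))
    # each spectrum pair: exactly one positive, at most one negative per mode
    expect_equal(anyDuplicated(pos$spec_mol_id[pos$split == "train"]), 0L)
    for (mode in c("train", "val", "test_rand", "test_diff")) {
      neg <- p[p$label == 0L & p$split == mode, ]
      expect_equal(anyDuplicated(neg$spec_mol_id), 0L)
    }
  }
})

test_that("test_diff negatives are below the similarity threshold or flagged", {
  set.seed(52)
  ds <- generate_dataset(40, seed = 52)
  p <- ds$manifest$pairs
  neg <- p[p$split == "test_diff" & p$label == 0L, ]
  for (r in seq_len(nrow(neg))) {
    a <- ds$graphs[[match(neg$mol_id[r], ds$molecules$id)]]
    b <- ds$graphs[[match(neg$spec_mol_id[r], ds$molecules$id)]]
    s <- structural_similarity(a, b)
    if (!neg$fallback[r]) expect_lt(s, ds$manifest$diff_threshold)
  }
})

test_that("dataset generation is reproducible to the byte", {
  ds1 <- generate_dataset(25, seed = 7, render = FALSE)
  ds2 <- generate_dataset(25, seed = 7, render = FALSE)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "m1"); f2 <- file.path(d, "m2")
  write_dataset(ds1, f1); write_dataset(ds2, f2)
  expect_identical(readLines(file.path(f1, "manifest.csv")),
                   readLines(file.path(f2, "manifest.csv")))
  expect_identical(ds1$molecules$smiles, ds2$molecules$smiles)
})

test_that("a nearest-neighbour baseline on noise-free profiles solves matching", {
  set.seed(53)
  ds <- generate_dataset(200, seed = 53, render = FALSE)
  spec_h <- render_spec("1H", noise_sd = 0, drift_amplitude = 0, seed = 1)
  spec_c <- render_spec("13C", noise_sd = 0, drift_amplitude = 0, seed = 1)
  profs <- t(vapply(ds$shifts, function(s) {
    c(render_profile(s, spec_h), render_profile(s, spec_c))
  }, numeric(512)))
  pairs <- ds$manifest$pairs
  test <- pairs[pairs$split %in% c("test_rand", "test_diff"), ]
  correct <- 0L
  for (r in seq_len(nrow(test))) {
    spec_prof <- profs[match(test$spec_mol_id[r], ds$molecules$id), ]
    d2 <- rowSums(sweep(profs, 2L, spec_prof)^2)
    nn <- ds$molecules$id[which.min(d2)]
    pred <- as.integer(nn == test$mol_id[r])
    correct <- correct + as.integer(pred == test$label[r])
  }
  expect_gt(correct / nrow(test), 0.9)
})

test_that("images and sidecars round-trip through the on-disk format", {
  ds <- generate_dataset(6, seed = 8)
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_true(file.exists(file.path(d, "shifts.csv")))
  expect_equal(length(list.files(d, pattern = "\\.png$")), 12L)
  img <- load_spectrum_image(file.path(d, "spec_0_1h.png"))
  expect_equal(dim(img), c(256L, 256L, 3L))
  expect_equal(img, ds$images[[1]]$h, tolerance = 1 / 255)
})
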