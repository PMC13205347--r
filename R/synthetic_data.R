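# Synthetic molecule--spectrum datasets with the statistical structure of the
# benchmark regime: C/N/O/H molecules with at most 16 heavy atoms,
# structure-determined 1H (2-12.05 ppm) and 13C (2-230 ppm) peak lists,
# rendered 256x256 spectral trace images with Lorentzian lineshapes, baseline
# drift and noise, 1:1 positive/negative pairs, molecule-level 8:1:1 splits
# and random vs structurally-dissimilar negative sampling.

element_valence <- c(C = 4L, N = 3L, O = 2L)

#' Sample a random valid molecule
#'
#' Grows a random spanning tree over heavy atoms (element frequencies biased
#' towards carbon), optionally closes a ring and upgrades bond orders where
#' both endpoints have free valence. The result is connected, respects
#' valence caps (C 4, N 3, O 2), has at least one carbon and at least one
#' hydrogen, and always passes [validate_molecule()].
#'
#' @param size_range Inclusive heavy-atom count range, within \[1, 16\].
#' @param schema Atom feature schema.
#' @return A `mol_graph`. Uses the current RNG stream; seed with `set.seed()`.
#' @export
sample_molecule <- function(size_range = c(4L, 16L), schema = atom_feature_schema()) {
  if (length(size_range) == 1L) size_range <- rep(size_range, 2L)
  if (size_range[1] < 1L || size_range[2] > 16L || size_range[1] > size_range[2])
    stop("size_range must lie within [1, 16]")
  repeat {
    n <- sample(size_range[1]:size_range[2], 1L)
    elements <- c("C", sample(c("C", "N", "O"), n - 1L, replace = TRUE,
                              prob = c(0.7, 0.15, 0.15)))[seq_len(n)]
    cap <- unname(element_valence[elements])
    used <- integer(n)
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
    ok <- TRUE
    for (i in seq_len(n)[-1]) {
      free <- which(used[seq_len(i - 1L)] < cap[seq_len(i - 1L)])
      if (!length(free)) { ok <- FALSE; break }
      j <- if (length(free) == 1L) free else sample(free, 1L)
      bonds <- rbind(bonds, data.frame(i = j, j = i, order = 1L))
      used[i] <- used[i] + 1L; used[j] <- used[j] + 1L
    }
    if (!ok) next
    # ring closure
    if (n >= 5L && stats::runif(1) < 0.35) {
      free <- which(used < cap)
      if (length(free) >= 2L) {
        pick <- sample(free, 2L)
        a <- min(pick); b <- max(pick)
        adjacent <- any((bonds$i == a & bonds$j == b) | (bonds$i == b & bonds$j == a))
        if (!adjacent && b - a >= 2L) {
          bonds <- rbind(bonds, data.frame(i = a, j = b, order = 1L))
          used[a] <- used[a] + 1L; used[b] <- used[b] + 1L
        }
      }
    }
    # bond-order upgrades
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      if (used[i] < cap[i] && used[j] < cap[j] && stats::runif(1) < 0.25) {
        bonds$order[r] <- 2L; used[i] <- used[i] + 1L; used[j] <- used[j] + 1L
        if (used[i] < cap[i] && used[j] < cap[j] && stats::runif(1) < 0.3) {
          bonds$order[r] <- 3L; used[i] <- used[i] + 1L; used[j] <- used[j] + 1L
        }
      }
    }
    g <- mol_graph(elements, bonds, schema = schema)
    if (sum(g$h_counts) == 0L) next # need at least one proton for the 1H spectrum
    if (validate_molecule(g)$ok) return(g)
  }
}

# Deterministic enumeration of distinct linear-chain C/N/O molecules, used
# when only dataset arithmetic (not chemistry) matters. The i-th molecule is
# a chain whose element sequence is the base-3 encoding of a counter;
# sequences lexicographically larger than their reversal are skipped so each
# structure appears once.
enumerate_molecules <- function(n, min_len = 4L, max_len = 16L) {
  syms <- c("C", "N", "O")
  out_sm <- character(0)
  for (len in min_len:max_len) {
    idx <- seq_len(3^len) - 1
    digs <- matrix(0L, length(idx), len)
    rem <- idx
    for (p in seq_len(len)) { digs[, p] <- rem %% 3; rem <- rem %/% 3 }
    chars <- matrix(syms[digs + 1L], nrow(digs), len)
    seqs <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
    revs <- do.call(paste0, as.data.frame(chars[, rev(seq_len(len)), drop = FALSE],
                                          stringsAsFactors = FALSE))
    out_sm <- c(out_sm, seqs[seqs <= revs]) # one representative per chain
    if (length(out_sm) >= n) break
  }
  if (length(out_sm) < n) stop("cannot enumerate ", n, " distinct chains up to length ", max_len)
  data.frame(id = seq_len(n) - 1L, smiles = out_sm[seq_len(n)], stringsAsFactors = FALSE)
}

chain_graph <- function(smiles, schema = atom_feature_schema()) {
  el <- strsplit(smiles, "")[[1]]
  n <- length(el)
  bonds <- if (n > 1L) data.frame(i = seq_len(n - 1L), j = 2:n, order = 1L)
           else data.frame(i = integer(), j = integer(), order = integer())
  mol_graph(el, bonds, schema = schema)
}

# ---- chemical shift model ----

#' Default additive chemical-shift model
#'
#' Base shift per (element, hybridisation) plus per-neighbour increments,
#' with a small deterministic perturbation hashed from the radius-2 atomic
#' environment so that distinct environments separate. A surrogate for real
#' acquisition: deterministic and structure-sensitive, not physically
#' accurate.
#'
#' @return List of model constants (all ppm).
#' @export
default_shift_model <- function() {
  list(
    c13_base = c(C_sp3 = 30, C_sp2 = 130, C_sp = 80, C_aromatic = 128),
    c13_incr = c(O = 25, N = 12, C = 9),
    c13_jitter = 3,
    h1_base = c(sp3 = 2.2, sp2 = 5.5, aromatic = 7.2, O = 4.5, N = 3.5),
    h1_incr = c(O = 1.2, N = 0.6, C = 0.15),
    h1_jitter = 0.15,
    h1_range = c(2, 12.05),
    c13_range = c(2, 230)
  )
}

# radius-2 environment identifiers reused from the fingerprint hashing
atom_env_ids <- function(graph, radius = 2L) {
  n <- graph$heavy_atom_count
  elc <- match(graph$atom_elements, c("C", "N", "O"), nomatch = 9L)
  ids <- hash_mix(hash_mix(hash_mix(elc, graph$degree), graph$h_counts),
                  as.integer(graph$aromatic))
  b <- graph$bond_orders
  nbrs <- lapply(seq_len(n), function(i) integer())
  ords <- lapply(seq_len(n), function(i) integer())
  for (r in seq_len(nrow(b))) {
    nbrs[[b$i[r]]] <- c(nbrs[[b$i[r]]], b$j[r]); ords[[b$i[r]]] <- c(ords[[b$i[r]]], b$order[r])
    nbrs[[b$j[r]]] <- c(nbrs[[b$j[r]]], b$i[r]); ords[[b$j[r]]] <- c(ords[[b$j[r]]], b$order[r])
  }
  for (r in seq_len(radius)) {
    new_ids <- numeric(n)
    for (i in seq_len(n)) {
      h <- hash_mix(r, ids[i])
      if (length(nbrs[[i]])) {
        pair <- hash_mix(ords[[i]] * 8, ids[nbrs[[i]]])
        for (p in sort(pair)) h <- hash_mix(h, p)
      }
      new_ids[i] <- h
    }
    ids <- new_ids
  }
  ids
}

#' Assign chemical shifts to a molecule
#'
#' Additive increment model: a base value per (element, hybridisation), a
#' contribution per heavy neighbour, and a deterministic environment-hash
#' perturbation, clamped to the nucleus range. 13C peaks are emitted for
#' carbon atoms; protons are grouped by their attached heavy atom with
#' weight equal to the attached-H count.
#'
#' @param graph A `mol_graph`.
#' @param model Shift-model constants from [default_shift_model()].
#' @return A `shift_table`: list with data frames `c13` (atom, shift_ppm) and
#'   `h1` (atom, shift_ppm, weight).
#' @export
assign_chemical_shifts <- function(graph, model = default_shift_model()) {
  n <- graph$heavy_atom_count
  env <- atom_env_ids(graph)
  jit <- (env %% 1000) / 1000 - 0.5 # deterministic in [-0.5, 0.5)
  nbr_el <- lapply(seq_len(n), function(i) character())
  b <- graph$bond_orders
  for (r in seq_len(nrow(b))) {
    nbr_el[[b$i[r]]] <- c(nbr_el[[b$i[r]]], graph$atom_elements[b$j[r]])
    nbr_el[[b$j[r]]] <- c(nbr_el[[b$j[r]]], graph$atom_elements[b$i[r]])
  }
  carbons <- which(graph$atom_elements == "C")
  c13 <- data.frame(atom = integer(), shift_ppm = numeric())
  if (length(carbons)) {
    base_key <- ifelse(graph$aromatic[carbons], "C_aromatic",
                       paste0("C_", graph$hybridization[carbons]))
    shift <- unname(model$c13_base[base_key])
    for (k in seq_along(carbons)) {
      i <- carbons[k]
      incr <- model$c13_incr[nbr_el[[i]]]
      shift[k] <- shift[k] + sum(incr, na.rm = TRUE) + jit[i] * 2 * model$c13_jitter
    }
    shift <- pmin(pmax(shift, model$c13_range[1]), model$c13_range[2])
    c13 <- data.frame(atom = carbons, shift_ppm = shift)
  }
  hat <- which(graph$h_counts > 0L)
  h1 <- data.frame(atom = integer(), shift_ppm = numeric(), weight = integer())
  if (length(hat)) {
    base_key <- ifelse(graph$atom_elements[hat] %in% c("O", "N"),
                       graph$atom_elements[hat],
                       ifelse(graph$aromatic[hat], "aromatic",
                              ifelse(graph$hybridization[hat] == "sp3", "sp3", "sp2")))
    shift <- unname(model$h1_base[base_key])
    for (k in seq_along(hat)) {
      i <- hat[k]
      incr <- model$h1_incr[nbr_el[[i]]]
      shift[k] <- shift[k] + sum(incr, na.rm = TRUE) + jit[i] * 2 * model$h1_jitter
    }
    shift <- pmin(pmax(shift, model$h1_range[1]), model$h1_range[2])
    h1 <- data.frame(atom = hat, shift_ppm = shift, weight = graph$h_counts[hat])
  }
  structure(list(c13 = c13, h1 = h1), class = "shift_table")
}

# ---- rendering ----

#' Rendering specification for one nucleus
#'
#' @param nucleus `"1H"` or `"13C"`.
#' @param image_size Image side length in pixels.
#' @param halfwidth Lorentzian half-width at half-maximum (ppm). Defaults:
#'   0.02 (1H), 0.5 (13C).
#' @param noise_sd Gaussian noise standard deviation on the intensity profile.
#' @param drift_amplitude Low-order-polynomial baseline drift amplitude.
#' @param seed Integer seed for the noise and drift draw (NULL: current RNG).
#' @return A `render_spec` list; ppm axis decreases left to right.
#' @export
render_spec <- function(nucleus = c("1H", "13C"), image_size = 256L,
                        halfwidth = NULL, noise_sd = 0.01,
                        drift_amplitude = 0.05, seed = NULL) {
  nucleus <- match.arg(nucleus)
  rng <- if (nucleus == "1H") c(2, 12.05) else c(2, 230)
  if (is.null(halfwidth)) halfwidth <- if (nucleus == "1H") 0.02 else 0.5
  structure(list(nucleus = nucleus, image_size = as.integer(image_size),
                 ppm_range = rng, halfwidth = halfwidth, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude, seed = seed),
            class = "render_spec")
}

#' Map chemical shifts to image columns
#'
#' Affine, monotone decreasing: the left edge is the high-ppm end.
#' @param ppm Chemical shifts (ppm).
#' @param spec A `render_spec`.
#' @return Column indices in 1..image_size.
#' @export
ppm_to_pixel <- function(ppm, spec) {
  frac <- (spec$ppm_range[2] - ppm) / (spec$ppm_range[2] - spec$ppm_range[1])
  pmin(pmax(ceiling(frac * spec$image_size), 1L), spec$image_size)
}

#' Noise-free 1-D intensity profile of a shift table
#'
#' Sum of multiplicity-weighted Lorentzians sampled at pixel-centre ppm
#' values, normalised to peak height 0.85.
#'
#' @param table A `shift_table`.
#' @param spec A `render_spec`.
#' @return Numeric vector of length `image_size`.
#' @export
render_profile <- function(table, spec) {
  peaks <- if (spec$nucleus == "1H") {
    data.frame(p = table$h1$shift_ppm, w = table$h1$weight)
  } else {
    if (nrow(table$c13)) data.frame(p = table$c13$shift_ppm, w = 1)
    else data.frame(p = numeric(), w = numeric())
  }
  prof <- numeric(spec$image_size)
  if (!nrow(peaks)) return(prof) # empty peak list: flat baseline
  j <- seq_len(spec$image_size)
  ppm <- spec$ppm_range[2] - (j - 0.5) / spec$image_size * diff(spec$ppm_range)
  g2 <- spec$halfwidth^2
  for (k in seq_len(nrow(peaks)))
    prof <- prof + peaks$w[k] * g2 / ((ppm - peaks$p[k])^2 + g2)
  prof / max(prof) * 0.85
}

#' Render a spectrum trace image
#'
#' The noise-free profile plus a smooth polynomial baseline drift plus
#' seeded Gaussian noise, clipped to \[0,1\] and drawn as a filled trace
#' (dark ink under the curve on a white background), replicated to three
#' channels.
#'
#' @param table A `shift_table`.
#' @param spec A `render_spec`.
#' @return `image_size` x `image_size` x 3 array in \[0,1\].
#' @export
render_spectrum_image <- function(table, spec) {
  prof <- render_profile(table, spec)
  n <- spec$image_size
  if (!is.null(spec$seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(spec$seed)
  }
  x <- seq(-1, 1, length.out = n)
  coef <- stats::rnorm(4L, sd = spec$drift_amplitude)
  drift <- coef[1] + coef[2] * x + coef[3] * x^2 + coef[4] * x^3
  prof <- prof + drift - min(c(drift, 0)) + stats::rnorm(n, sd = spec$noise_sd)
  prof <- pmin(pmax(prof, 0), 1)
  rows <- matrix((n - seq_len(n) + 0.5) / n, n, n) # row 1 = top
  img <- ifelse(rows <= matrix(prof, n, n, byrow = TRUE), 0, 1)
  array(img, dim = c(n, n, 3L))
}

#' Load a spectrum image from PNG
#'
#' Scales to \[0,1\], replicates grayscale to 3 channels and resizes
#' (bilinear) to the target side length when needed.
#'
#' @param path PNG file.
#' @param size Target side length (default 256).
#' @return size x size x 3 array.
#' @export
load_spectrum_image <- function(path, size = 256L) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[1] != size || dim(img)[2] != size) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("resizing requires the EBImage package; provide ", size, "x", size, " input")
    img <- EBImage::imageData(EBImage::resize(EBImage::Image(img, colormode = "Color"),
                                              w = size, h = size))
    img <- aperm(img, c(2L, 1L, 3L)) # EBImage stores x,y; return row, col
  }
  img
}

write_spectrum_png <- function(img, path) {
  png::writePNG(img[, , 1L], path) # grayscale content; channels identical
  invisible(path)
}

# ---- pairing and splits ----

#' Build a paired positive/negative dataset manifest
#'
#' One positive pair per molecule and one negative per positive (1:1).
#' Splits are molecule-level 8:1:1 (train/val/test); the test molecules are
#' evaluated under two negative-sampling modes: `test_rand` (uniform random
#' other molecule) and `test_diff` (a molecule with fingerprint Tanimoto
#' similarity below `diff_threshold`; when no candidate qualifies the least
#' similar one is used and flagged `fallback`). Negatives are drawn within
#' split, and each molecule's spectrum pair is used in exactly one positive
#' and at most one negative per mode.
#'
#' @param molecules Data frame with columns `id` and `smiles`.
#' @param graphs Optional list of `mol_graph` objects aligned with
#'   `molecules` (built from the SMILES when omitted; needed for `test_diff`).
#' @param seed Integer seed controlling shuffling and negative draws.
#' @param diff_threshold Tanimoto threshold for `test_diff` negatives.
#' @param ratios Split proportions (train, val, test); default 8:1:1.
#' @return A `dataset_manifest`: list with `pairs` (pair records), `spectra`
#'   (two spectrum-image records per molecule) and `splits`.
#' @export
build_pair_dataset <- function(molecules, graphs = NULL, seed = 1L,
                               diff_threshold = 0.2, ratios = c(8, 1, 1)) {
  n <- nrow(molecules)
  if (n < 5L) stop("need at least 5 molecules")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  spectra <- data.frame(
    mol_id = rep(molecules$id, each = 2L),
    nucleus = rep(c("1H", "13C"), n),
    image = paste0("spec_", rep(molecules$id, each = 2L), "_",
                   rep(c("1h", "13c"), n), ".png"),
    stringsAsFactors = FALSE)
  ord <- sample.int(n)
  p <- ratios / sum(ratios)
  n_train <- floor(n * p[1]); n_val <- floor(n * p[2])
  split_of <- character(n)
  split_of[ord[seq_len(n_train)]] <- "train"
  split_of[ord[n_train + seq_len(n_val)]] <- "val"
  split_of[ord[(n_train + n_val + 1L):n]] <- "test"
  # within-split derangement; a split too small to self-pair draws its
  # negatives from the remaining molecules instead
  derange <- function(idx) {
    if (length(idx) < 2L) {
      pool <- setdiff(seq_len(n), idx)
      return(sample(pool, length(idx)))
    }
    repeat {
      s <- sample(idx)
      if (!any(s == idx)) return(s)
    }
  }
  rows <- list()
  add_pairs <- function(idx, split_tag, neg_mode, fps = NULL) {
    if (!length(idx)) return(invisible(NULL))
    neg <- if (neg_mode == "diff" && length(idx) >= 2L) {
      assign_diff_negatives(idx, fps, diff_threshold)
    } else if (neg_mode == "diff") { # too few test molecules to compare
      list(target = sample(setdiff(seq_len(n), idx), length(idx)),
           fallback = rep(TRUE, length(idx)))
    } else list(target = derange(idx), fallback = rep(FALSE, length(idx)))
    # interleave positive and negative records per molecule
    k <- length(idx)
    ord <- as.vector(rbind(seq_len(k), k + seq_len(k)))
    block <- data.frame(
      mol_id = rep(molecules$id[idx], 2L),
      spec_mol_id = c(molecules$id[idx], molecules$id[neg$target]),
      smiles = rep(molecules$smiles[idx], 2L),
      label = rep(c(1L, 0L), each = k),
      neg_mode = rep(c("none", neg_mode), each = k),
      split = split_tag,
      fallback = c(rep(FALSE, k), neg$fallback),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <<- block[ord, ]
  }
  add_pairs(which(split_of == "train"), "train", "rand")
  add_pairs(which(split_of == "val"), "val", "rand")
  test_idx <- which(split_of == "test")
  add_pairs(test_idx, "test_rand", "rand")
  fps <- NULL
  if (length(test_idx)) {
    if (is.null(graphs)) graphs <- c() # resolved below
    gset <- if (length(graphs)) graphs[test_idx]
            else smiles_to_graph_list(molecules$smiles[test_idx])
    fps <- lapply(gset, morgan_fingerprint)
    names(fps) <- as.character(test_idx)
  }
  add_pairs(test_idx, "test_diff", "diff", fps = fps)
  pairs <- do.call(rbind, rows)
  pairs <- cbind(pair_id = seq_len(nrow(pairs)) - 1L, pairs)
  pairs$h_image <- paste0("spec_", pairs$spec_mol_id, "_1h.png")
  pairs$c_image <- paste0("spec_", pairs$spec_mol_id, "_13c.png")
  structure(list(pairs = pairs, spectra = spectra,
                 splits = data.frame(id = molecules$id, split = split_of),
                 seed = seed, diff_threshold = diff_threshold),
            class = "dataset_manifest")
}

# Structurally-dissimilar negative assignment by rejection sampling: for each
# molecule, candidates are drawn (each used at most once) until one falls
# below the similarity threshold; after max_tries the least similar candidate
# tried is used and flagged as fallback.
assign_diff_negatives <- function(idx, fps, threshold, max_tries = 50L) {
  k <- length(idx)
  target <- integer(k)
  fallback <- logical(k)
  used <- logical(k)
  for (a in seq_len(k)) {
    avail <- which(!used & seq_len(k) != a)
    if (!length(avail)) { # exhausted: reuse an arbitrary other molecule
      target[a] <- idx[if (a == 1L) 2L else 1L]; fallback[a] <- TRUE; next
    }
    cand <- if (length(avail) == 1L) avail else sample(avail, min(max_tries, length(avail)))
    best <- NA_integer_; best_sim <- Inf
    for (b in cand) {
      s <- structural_similarity(fps[[a]], fps[[b]])
      if (s < best_sim) { best_sim <- s; best <- b }
      if (s < threshold) break
    }
    target[a] <- idx[best]
    fallback[a] <- best_sim >= threshold
    used[best] <- TRUE
  }
  if (any(fallback))
    warning(sum(fallback), " test_diff negative(s) above the similarity ",
            "threshold; least-similar fallback used and flagged")
  list(target = target, fallback = fallback)
}

# ---- end-to-end generation ----

#' Generate a complete synthetic dataset
#'
#' Samples distinct molecules, assigns chemical shifts, renders paired
#' 1H/13C images, and builds the pair manifest with splits.
#'
#' @param n_molecules Number of distinct molecules.
#' @param seed Master seed; all randomness (sampling, rendering, pairing)
#'   derives from it.
#' @param render Render images (set `FALSE` for manifest-only arithmetic).
#' @param size_range Heavy-atom count range for the sampler.
#' @param diff_threshold Tanimoto threshold for `test_diff`.
#' @param noise_sd,drift_amplitude Rendering noise parameters.
#' @return An `nmr_dataset`: list with `molecules`, `graphs`, `shifts`,
#'   `images` (list of per-molecule `list(h, c)` arrays or NULL),
#'   `manifest` (a `dataset_manifest`) and the generation settings.
#' @export
generate_dataset <- function(n_molecules, seed = 1L, render = TRUE,
                             size_range = c(4L, 16L), diff_threshold = 0.2,
                             noise_sd = 0.01, drift_amplitude = 0.05) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  graphs <- list()
  seen <- character()
  while (length(graphs) < n_molecules) {
    g <- sample_molecule(size_range)
    key <- graph_key(g)
    if (key %in% seen) next
    seen <- c(seen, key)
    graphs[[length(graphs) + 1L]] <- g
  }
  smiles <- graphs_to_smiles(graphs)
  molecules <- data.frame(id = seq_len(n_molecules) - 1L, smiles = smiles,
                          stringsAsFactors = FALSE)
  shifts <- lapply(graphs, assign_chemical_shifts)
  images <- NULL
  if (render) {
    images <- vector("list", n_molecules)
    for (i in seq_len(n_molecules)) {
      sh <- (seed * 7919 + i * 2L) %% 2147483647
      sc <- (seed * 7919 + i * 2L + 1L) %% 2147483647
      images[[i]] <- list(
        h = render_spectrum_image(shifts[[i]], render_spec("1H", noise_sd = noise_sd,
              drift_amplitude = drift_amplitude, seed = sh)),
        c = render_spectrum_image(shifts[[i]], render_spec("13C", noise_sd = noise_sd,
              drift_amplitude = drift_amplitude, seed = sc)))
    }
  }
  manifest <- build_pair_dataset(molecules, graphs = graphs, seed = seed,
                                 diff_threshold = diff_threshold)
  structure(list(molecules = molecules, graphs = graphs, shifts = shifts,
                 images = images, manifest = manifest, seed = seed,
                 size_range = size_range),
            class = "nmr_dataset")
}

# Structure key for deduplication: canonical within this package via the
# sorted radius-2 environment multiset (cheap, no external call).
graph_key <- function(g) {
  paste(sort(atom_env_ids(g)), collapse = ",")
}

# SMILES for sampled graphs: write V2000 blocks and batch-convert through
# OpenBabel to canonical SMILES.
graphs_to_smiles <- function(graphs, chunk = 2000L) {
  out <- character(length(graphs))
  pos <- 1L
  while (pos <= length(graphs)) {
    idx <- pos:min(pos + chunk - 1L, length(graphs))
    sdf <- paste(vapply(graphs[idx], graph_to_molblock, ""), collapse = "")
    res <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", sdf))
    sm <- vapply(strsplit(strsplit(res, "\n")[[1]], "\t"), `[`, "", 1L)
    if (length(sm) != length(idx)) stop("SMILES conversion dropped molecules")
    out[idx] <- sm
    pos <- pos + chunk
  }
  out
}

graph_to_molblock <- function(g) {
  n <- g$heavy_atom_count
  b <- g$bond_orders
  lines <- c("", " nmrmatch", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)))
  for (i in seq_len(n))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, g$atom_elements[i]))
  for (r in seq_len(nrow(b)))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", b$i[r], b$j[r], b$order[r]))
  chg <- which(g$charges != 0L)
  if (length(chg))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, g$charges[chg]), collapse = "")))
  paste0(paste(c(lines, "M  END", "$$$$"), collapse = "\n"), "\n")
}

#' Write a dataset to disk
#'
#' Emits PNG images, `manifest.csv`, `shifts.csv` and `config.yaml`.
#'
#' @param ds An `nmr_dataset` with rendered images.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(ds$images)) {
    for (i in seq_len(nrow(ds$molecules))) {
      id <- ds$molecules$id[i]
      write_spectrum_png(ds$images[[i]]$h, file.path(dir, paste0("spec_", id, "_1h.png")))
      write_spectrum_png(ds$images[[i]]$c, file.path(dir, paste0("spec_", id, "_13c.png")))
    }
  }
  utils::write.csv(ds$manifest$pairs, file.path(dir, "manifest.csv"), row.names = FALSE)
  sh <- do.call(rbind, lapply(seq_along(ds$shifts), function(i) {
    s <- ds$shifts[[i]]
    rbind(
      if (nrow(s$c13)) data.frame(mol_id = ds$molecules$id[i], nucleus = "13C",
                                  atom = s$c13$atom, shift_ppm = s$c13$shift_ppm, weight = 1L),
      if (nrow(s$h1)) data.frame(mol_id = ds$molecules$id[i], nucleus = "1H",
                                 atom = s$h1$atom, shift_ppm = s$h1$shift_ppm,
                                 weight = s$h1$weight))
  }))
  utils::write.csv(sh, file.path(dir, "shifts.csv"), row.names = FALSE)
  yaml::write_yaml(list(seed = ds$seed, n_molecules = nrow(ds$molecules),
                        size_range = as.integer(ds$size_range),
                        diff_threshold = ds$manifest$diff_threshold),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
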