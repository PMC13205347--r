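# Molecular graphs: SMILES input, atom featurisation, composition validation
# and fingerprint similarity.
#
# Molecules are heavy-atom graphs: hydrogens are folded into a per-atom
# attached-H count (the spectra, not the graph, carry the 1H information).
# SMILES parsing and canonicalisation are delegated to OpenBabel via
# ChemmineOB; the V2000 connection tables it emits are read by a small text
# parser here. OpenBabel kekulizes on output, so aromaticity is re-perceived
# from ring membership and pi-electron counting.

#' Atom feature schema
#'
#' Defines the fixed-width per-atom feature layout used by the graph encoder:
#' element one-hot over C/N/O (3), heavy-atom degree one-hot 0--4 (5),
#' attached-hydrogen count one-hot 0--4 (5), aromatic flag (1), formal charge
#' one-hot over -1/0/+1 (3), hybridisation one-hot sp/sp2/sp3/other (4), plus
#' zero padding to a total width divisible by the attention head count.
#'
#' @param d Total feature width. Must be at least the sum of the block widths
#'   (21); the remainder is zero padding. The default 24 is divisible by the
#'   8 attention heads.
#' @return An object of class `atom_schema` with elements `vocab`, `blocks`
#'   (named widths) and `d`.
#' @export
atom_feature_schema <- function(d = 24L) {
  blocks <- c(element = 3L, degree = 5L, h_count = 5L, aromatic = 1L,
              charge = 3L, hybridization = 4L)
  stopifnot(d >= sum(blocks))
  structure(list(vocab = c("C", "N", "O"), blocks = c(blocks, padding = d - sum(blocks)),
                 d = as.integer(d)),
            class = "atom_schema")
}

# ---- V2000 connection-table text parsing ----

# Split a multi-record SDF string into per-molecule blocks.
split_sdf_records <- function(sdf_text) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) return(list(lines))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mapply(function(s, e) lines[s:(e - 1L)], starts, ends, SIMPLIFY = FALSE)
}

# Parse one V2000 molblock (character vector of lines) into elements,
# formal charges and a bond table.
parse_v2000 <- function(lines) {
  if (length(lines) < 4L) stop("molblock too short")
  counts <- lines[4L]
  natoms <- as.integer(substr(counts, 1L, 3L))
  nbonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(natoms)) stop("bad V2000 counts line")
  elements <- character(natoms)
  for (i in seq_len(natoms)) {
    ln <- lines[4L + i]
    elements[i] <- trimws(substr(ln, 32L, 34L))
  }
  bonds <- if (nbonds > 0L) {
    bl <- lines[(4L + natoms + 1L):(4L + natoms + nbonds)]
    data.frame(
      i = as.integer(substr(bl, 1L, 3L)),
      j = as.integer(substr(bl, 4L, 6L)),
      order = as.integer(substr(bl, 7L, 9L))
    )
  } else data.frame(i = integer(), j = integer(), order = integer())
  charges <- integer(natoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))), "\\s+")[[1]])
    n <- f[1L]
    for (k in seq_len(n)) {
      charges[f[2L * k]] <- f[2L * k + 1L]
    }
  }
  list(elements = elements, charges = charges, bonds = bonds)
}

# ---- ring perception ----

# All simple cycles up to max_len, each reported once as a sorted atom set
# with the traversal order retained. Graphs here have <= 16 nodes.
find_rings <- function(adj, max_len = 7L) {
  n <- length(adj)
  rings <- list()
  seen <- character()
  walk <- function(start, path) {
    cur <- path[length(path)]
    for (nb in adj[[cur]]) {
      if (nb == start && length(path) >= 3L) {
        key <- paste(sort(path), collapse = ",")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (nb > start && !(nb %in% path) && length(path) < max_len) {
        walk(start, c(path, nb))
      }
    }
  }
  for (s in seq_len(n)) walk(s, s)
  rings
}

# Aromatic perception on a kekulized graph: a ring of size 5-7 is aromatic
# when every member is sp2-capable (has an in-ring double bond, an exocyclic
# double bond, or is N/O with only single bonds, donating a lone pair) and
# the in-ring pi-electron count satisfies Hueckel's 4n+2.
perceive_aromatic <- function(elements, bonds, n) {
  arom <- logical(n)
  if (!nrow(bonds) || n < 3L) return(arom)
  adj <- lapply(seq_len(n), function(i) integer())
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  bkey <- function(i, j) paste(min(i, j), max(i, j))
  order_of <- stats::setNames(bonds$order, mapply(bkey, bonds$i, bonds$j))
  has_double <- logical(n)
  for (r in seq_len(nrow(bonds))) if (bonds$order[r] >= 2L) {
    has_double[bonds$i[r]] <- TRUE; has_double[bonds$j[r]] <- TRUE
  }
  for (ring in find_rings(adj)) {
    len <- length(ring)
    if (len < 5L || len > 7L) next
    nxt <- c(ring[-1L], ring[1L])
    ring_orders <- unname(order_of[mapply(bkey, ring, nxt)])
    pi_e <- 2L * sum(ring_orders == 2L)
    ok <- TRUE
    for (a in ring) {
      in_ring_double <- any(ring_orders[ring == a | nxt == a] == 2L)
      if (in_ring_double) next
      if (elements[a] %in% c("N", "O") && !has_double[a]) {
        pi_e <- pi_e + 2L # lone-pair donor
      } else if (!has_double[a]) {
        ok <- FALSE; break # sp3 centre breaks conjugation
      }
      # carbon with exocyclic double bond: sp2-capable, contributes 0
    }
    if (ok && pi_e %% 4L == 2L) arom[ring] <- TRUE
  }
  arom
}

# ---- graph construction ----

standard_valence <- c(C = 4L, N = 3L, O = 2L, H = 1L)

#' Build a molecular graph from atoms and bonds
#'
#' Low-level constructor used by both the SMILES reader and the molecule
#' sampler. Hydrogens listed explicitly are folded into the attached-H count
#' of their heavy neighbour; remaining free valence is filled with implicit
#' hydrogens.
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param bonds Data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2 or 3; kekulized).
#' @param charges Integer vector of formal charges (default all zero).
#' @param schema Atom feature schema from [atom_feature_schema()].
#' @param strict Error when a heavy element lies outside the schema
#'   vocabulary. With `strict = FALSE` the element one-hot is left all-zero so
#'   that [validate_molecule()] can report the violation.
#' @return A `mol_graph`: list with `node_features` (|V| x d matrix), `edges`
#'   (directed-symmetric two-column index matrix), `atom_elements`, `charges`,
#'   `h_counts`, `aromatic`, `hybridization`, `bond_orders`,
#'   `heavy_atom_count` and the `schema`.
#' @export
mol_graph <- function(elements, bonds, charges = integer(length(elements)),
                      schema = atom_feature_schema(), strict = TRUE) {
  stopifnot(is.character(elements), length(elements) >= 1L)
  keep <- elements != "H"
  if (!all(keep)) {
    # fold explicit hydrogens into their heavy neighbour counts
    hmap <- cumsum(keep)
    explicit_h <- integer(sum(keep))
    newb <- bonds[0, ]
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      if (!keep[i] && !keep[j]) next
      if (!keep[i]) { explicit_h[hmap[j]] <- explicit_h[hmap[j]] + 1L; next }
      if (!keep[j]) { explicit_h[hmap[i]] <- explicit_h[hmap[i]] + 1L; next }
      newb <- rbind(newb, data.frame(i = hmap[i], j = hmap[j], order = bonds$order[r]))
    }
    bonds <- newb
    charges <- charges[keep]
    elements <- elements[keep]
  } else explicit_h <- integer(length(elements))
  n <- length(elements)
  if (nrow(bonds)) {
    stopifnot(all(bonds$i >= 1L & bonds$i <= n), all(bonds$j >= 1L & bonds$j <= n))
  }
  unknown <- setdiff(unique(elements), c(schema$vocab))
  if (strict && length(unknown))
    stop("element(s) outside vocabulary {", paste(schema$vocab, collapse = ","),
         "}: ", paste(unknown, collapse = ","))
  degree <- integer(n); valence_used <- integer(n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]; o <- bonds$order[r]
    degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
    valence_used[i] <- valence_used[i] + o; valence_used[j] <- valence_used[j] + o
  }
  vmax <- unname(standard_valence[elements])
  vmax[is.na(vmax)] <- valence_used[is.na(vmax)] # unknown element: no implicit H
  vmax <- vmax + ifelse(elements == "N", charges,
                 ifelse(elements == "O", charges,
                 ifelse(elements == "C", -abs(charges), 0L)))
  h_counts <- pmax(vmax - valence_used - explicit_h, 0L) + explicit_h
  aromatic <- perceive_aromatic(elements, bonds, n)
  n_double <- integer(n); n_triple <- integer(n)
  for (r in seq_len(nrow(bonds))) {
    if (bonds$order[r] == 2L) {
      n_double[bonds$i[r]] <- n_double[bonds$i[r]] + 1L
      n_double[bonds$j[r]] <- n_double[bonds$j[r]] + 1L
    } else if (bonds$order[r] == 3L) {
      n_triple[bonds$i[r]] <- n_triple[bonds$i[r]] + 1L
      n_triple[bonds$j[r]] <- n_triple[bonds$j[r]] + 1L
    }
  }
  hybrid <- ifelse(n_triple > 0L | n_double >= 2L, "sp",
            ifelse(n_double == 1L | aromatic, "sp2", "sp3"))
  edges <- if (nrow(bonds)) {
    e <- rbind(cbind(bonds$i, bonds$j), cbind(bonds$j, bonds$i))
    storage.mode(e) <- "integer"
    e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  } else matrix(integer(), 0L, 2L)
  g <- structure(list(
    node_features = NULL, edges = edges, atom_elements = elements,
    charges = as.integer(charges), h_counts = as.integer(h_counts),
    degree = degree, aromatic = aromatic, hybridization = hybrid,
    bond_orders = bonds, heavy_atom_count = n, schema = schema
  ), class = "mol_graph")
  g$node_features <- featurize_atoms(g, schema)
  g
}

featurize_atoms <- function(g, schema) {
  n <- g$heavy_atom_count
  X <- matrix(0, n, schema$d)
  off <- 0L
  el <- match(g$atom_elements, schema$vocab)
  ok <- !is.na(el)
  X[cbind(which(ok), el[ok])] <- 1
  off <- off + 3L
  X[cbind(seq_len(n), off + pmin(g$degree, 4L) + 1L)] <- 1
  off <- off + 5L
  X[cbind(seq_len(n), off + pmin(g$h_counts, 4L) + 1L)] <- 1
  off <- off + 5L
  X[, off + 1L] <- as.numeric(g$aromatic)
  off <- off + 1L
  ch <- g$charges
  okc <- ch >= -1L & ch <= 1L
  X[cbind(which(okc), off + ch[okc] + 2L)] <- 1
  off <- off + 3L
  hy <- match(g$hybridization, c("sp", "sp2", "sp3"))
  hy[is.na(hy)] <- 4L
  X[cbind(seq_len(n), off + hy)] <- 1
  X
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("mol_graph: %d heavy atoms (%s), %d directed edges, d = %d\n",
              x$heavy_atom_count, paste(x$atom_elements, collapse = ""),
              nrow(x$edges), x$schema$d))
  invisible(x)
}

# ---- SMILES input ----

parsed_to_graph <- function(p, schema, strict) {
  mol_graph(p$elements, p$bonds, p$charges, schema = schema, strict = strict)
}

#' Parse a SMILES string into a molecular graph
#'
#' Conversion goes through OpenBabel (SMILES to a V2000 connection table);
#' one node per heavy atom, hydrogens folded into the attached-H feature,
#' bonds stored as a directed-symmetric edge list.
#'
#' @param smiles A single SMILES string.
#' @param schema Atom feature schema.
#' @param strict Error on elements outside the C/N/O vocabulary (see
#'   [mol_graph()]).
#' @return A `mol_graph`.
#' @export
smiles_to_graph <- function(smiles, schema = atom_feature_schema(), strict = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdf <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"))),
    error = function(e) "")
  recs <- tryCatch(parse_v2000(split_sdf_records(sdf)[[1L]]),
                   error = function(e) NULL)
  if (is.null(recs) || length(recs$elements) == 0L)
    stop("failed to parse SMILES: '", smiles, "'")
  parsed_to_graph(recs, schema, strict)
}

# Batched SMILES parsing (one OpenBabel call per chunk); falls back to
# per-molecule parsing when a chunk silently drops records.
smiles_to_graph_list <- function(smiles, schema = atom_feature_schema(),
                                 strict = TRUE, chunk = 2000L) {
  out <- vector("list", length(smiles))
  pos <- 1L
  while (pos <= length(smiles)) {
    idx <- pos:min(pos + chunk - 1L, length(smiles))
    sdf <- suppressWarnings(
      ChemmineOB::convertFormat("SMI", "SDF", paste0(paste(smiles[idx], collapse = "\n"), "\n")))
    recs <- split_sdf_records(sdf)
    recs <- recs[vapply(recs, function(r) length(r) >= 4L, TRUE)]
    if (length(recs) == length(idx)) {
      out[idx] <- lapply(recs, function(r) parsed_to_graph(parse_v2000(r), schema, strict))
    } else {
      out[idx] <- lapply(smiles[idx], smiles_to_graph, schema = schema, strict = strict)
    }
    pos <- pos + chunk
  }
  out
}

#' Canonical SMILES via OpenBabel
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  out <- suppressWarnings(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(paste(smiles, collapse = "\n"), "\n")))
  vapply(strsplit(strsplit(out, "\n")[[1]], "\t"), `[`, "", 1L)
}

#' Read molecules from a SMILES text file or CSV
#'
#' Plain text files carry one SMILES per line; CSV files must have a `smiles`
#' column and may carry an `id` column (otherwise zero-based line order).
#'
#' @param path Input file.
#' @return Data frame with columns `id` and `smiles`.
#' @export
read_smiles_input <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df)) stop("CSV input needs a 'smiles' column")
    if (!"id" %in% names(df)) df$id <- seq_len(nrow(df)) - 1L
    df[, c("id", "smiles")]
  } else {
    sm <- readLines(path, warn = FALSE)
    sm <- sm[nzchar(trimws(sm))]
    data.frame(id = seq_along(sm) - 1L, smiles = trimws(sm))
  }
}

# ---- validation ----

#' Validate a molecule against the dataset composition constraints
#'
#' Accepts exactly the molecules with at most `max_heavy` heavy atoms whose
#' heavy elements all lie in C/N/O. Total function: never errors.
#'
#' @param graph A `mol_graph`.
#' @param max_heavy Heavy-atom cap (default 16).
#' @return List with `ok` (logical) and `reason` (`NA`, `"size"` or
#'   `"element"`).
#' @export
validate_molecule <- function(graph, max_heavy = 16L) {
  stopifnot(inherits(graph, "mol_graph"))
  if (!all(graph$atom_elements %in% c("C", "N", "O")))
    return(list(ok = FALSE, reason = "element"))
  if (graph$heavy_atom_count > max_heavy)
    return(list(ok = FALSE, reason = "size"))
  list(ok = TRUE, reason = NA_character_)
}

# ---- fingerprints and similarity ----

# Deterministic integer mixing in double precision (exact below 2^53).
hash_mix <- function(a, b) ((a * 1000003 + b) %% 2147483647)

#' Hashed circular substructure fingerprint
#'
#' Morgan-style iterative neighbourhood hashing: the radius-0 invariant mixes
#' element, degree, attached-H count, charge and aromaticity; each round
#' rehashes an atom's identifier with the sorted (bond order, neighbour
#' identifier) list. Identifiers from all radii are folded onto `nbits` bits.
#'
#' @param graph A `mol_graph`.
#' @param radius Neighbourhood radius (default 2).
#' @param nbits Fingerprint length in bits (default 1024).
#' @return Sorted integer vector of on-bit positions (0-based).
#' @export
morgan_fingerprint <- function(graph, radius = 2L, nbits = 1024L) {
  n <- graph$heavy_atom_count
  elc <- match(graph$atom_elements, c("C", "N", "O"), nomatch = 9L)
  ids <- hash_mix(hash_mix(hash_mix(hash_mix(elc, graph$degree),
                                    graph$h_counts),
                           graph$charges + 5),
                  as.integer(graph$aromatic))
  nbrs <- lapply(seq_len(n), function(i) integer())
  ords <- lapply(seq_len(n), function(i) integer())
  b <- graph$bond_orders
  for (r in seq_len(nrow(b))) {
    nbrs[[b$i[r]]] <- c(nbrs[[b$i[r]]], b$j[r]); ords[[b$i[r]]] <- c(ords[[b$i[r]]], b$order[r])
    nbrs[[b$j[r]]] <- c(nbrs[[b$j[r]]], b$i[r]); ords[[b$j[r]]] <- c(ords[[b$j[r]]], b$order[r])
  }
  all_ids <- ids
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
    all_ids <- c(all_ids, ids)
  }
  sort(unique(as.integer(all_ids %% nbits)))
}

#' Tanimoto structural similarity between two molecules
#'
#' Intersection-over-union of hashed circular fingerprint bit sets
#' (radius 2, 1024 bits). Symmetric; 1 for identical canonical structures.
#'
#' @param a,b `mol_graph` objects, or precomputed fingerprints (integer
#'   vectors of on bits).
#' @return Similarity in \[0, 1\].
#' @export
structural_similarity <- function(a, b) {
  fa <- if (inherits(a, "mol_graph")) morgan_fingerprint(a) else a
  fb <- if (inherits(b, "mol_graph")) morgan_fingerprint(b) else b
  u <- length(union(fa, fb))
  if (u == 0L) return(1)
  length(intersect(fa, fb)) / u
}

# ---- debug output ----

#' Write node and edge tables of a graph as CSV
#' @param graph A `mol_graph`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the two file paths.
#' @export
write_graph_tables <- function(graph, dir, prefix = "mol") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- data.frame(index = seq_len(graph$heavy_atom_count) - 1L,
                      element = graph$atom_elements, degree = graph$degree,
                      h_count = graph$h_counts, aromatic = graph$aromatic,
                      charge = graph$charges, hybridization = graph$hybridization)
  nf <- file.path(dir, paste0(prefix, "_nodes.csv"))
  ef <- file.path(dir, paste0(prefix, "_edges.csv"))
  utils::write.csv(cbind(nodes, graph$node_features), nf, row.names = FALSE)
  utils::write.csv(data.frame(i = graph$edges[, 1L] - 1L, j = graph$edges[, 2L] - 1L),
                   ef, row.names = FALSE)
  invisible(c(nf, ef))
}
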