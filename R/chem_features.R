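# Drug featurization: SMILES in, three modalities out — circular fingerprint
# bit vectors, character-level token sequences, and heavy-atom molecular
# graphs. SMILES parsing, canonicalisation, aromaticity perception and
# hybridisation assignment are delegated to OpenBabel via ChemmineOB; ring
# perception uses igraph on the bond graph.

.ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")
.HYB_LEVELS <- c("1", "2", "3", "ar", "other")
.BOND_LEVELS <- c("1", "2", "3", "ar", "other")

#' Atom and bond feature schema
#'
#' Describes the columns of `node_features` and `edge_features` in a
#' [smiles_to_graph()] result so encoders can assert input widths. Atoms:
#' one-hot element (top elements + other), one-hot degree (1..4, 5+), formal
#' charge, aromatic flag, one-hot hybridisation. Bonds: one-hot bond order
#' (single/double/triple/aromatic/other), conjugation flag, ring flag.
#'
#' @return A list with `d_atom`, `d_bond`, `version` and the level sets.
#' @export
atom_feature_schema <- function() {
  list(
    version = "1",
    elements = .ELEMENTS,
    hybridisations = .HYB_LEVELS,
    bond_orders = .BOND_LEVELS,
    d_atom = length(.ELEMENTS) + 1L + 5L + 1L + 1L + length(.HYB_LEVELS),
    d_bond = length(.BOND_LEVELS) + 2L
  )
}

#' Canonicalise a SMILES string
#'
#' Two spellings of the same molecule map to the same canonical string, which
#' makes canonical SMILES usable as a deduplication key.
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES string.
#' @examples
#' canonicalize_smiles("OCC") == canonicalize_smiles("CCO")
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("empty SMILES string")
  out <- ChemmineOB::convertFormat("SMI", "CAN", smiles)
  out <- sub("[ \t].*$", "", trimws(out))
  if (!nzchar(out)) stop("unparsable SMILES: '", smiles, "'")
  out
}

#' Is a SMILES string parsable?
#' @param smiles A single SMILES string.
#' @return Logical.
#' @export
is_valid_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) return(FALSE)
  !inherits(try(canonicalize_smiles(smiles), silent = TRUE), "try-error")
}

# Scan a SMILES string and return its atom tokens in order of appearance.
# Needed to align formal charges (only visible in the string) with the atom
# order of the converted structure, which OpenBabel preserves.
.smiles_atom_tokens <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  atoms <- character(0)
  i <- 1L
  n <- length(chars)
  two <- c("Cl", "Br")
  organic <- c("B", "C", "N", "O", "S", "P", "F", "I")
  aromatic <- c("b", "c", "n", "o", "s", "p")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      atoms <- c(atoms, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% two) {
      atoms <- c(atoms, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch %in% organic || ch %in% aromatic) {
      atoms <- c(atoms, ch)
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  atoms
}

.formal_charge <- function(atom_token) {
  if (!startsWith(atom_token, "[")) return(0L)
  body <- gsub("^\\[|\\]$", "", atom_token)
  m <- regmatches(body, regexpr("[+-]+[0-9]*$|[+-][0-9]*", body))
  if (length(m) == 0L || !nzchar(m)) return(0L)
  sign <- if (startsWith(m, "-")) -1L else 1L
  digits <- gsub("[+-]", "", m)
  mag <- if (nzchar(digits)) as.integer(digits) else nchar(gsub("[0-9]", "", m))
  sign * mag
}

# Parse a SMILES via an OpenBabel MOL2 conversion into atoms/bonds tables.
# MOL2 atom types carry hybridisation ("C.3") and aromaticity ("C.ar"); bond
# types include "ar" (aromatic) and "am" (amide). Hydrogens stay implicit.
.parse_mol <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("empty SMILES string")
  txt <- ChemmineOB::convertFormat("SMI", "MOL2", smiles)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  ai <- which(lines == "@<TRIPOS>ATOM")
  bi <- which(lines == "@<TRIPOS>BOND")
  if (length(ai) == 0L) stop("unparsable SMILES: '", smiles, "'")
  a_end <- if (length(bi)) bi - 1L else length(lines)
  atom_lines <- lines[(ai + 1L):a_end]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  if (length(atom_lines) == 0L) stop("unparsable SMILES: '", smiles, "'")
  af <- strsplit(trimws(atom_lines), "[ \t]+")
  type <- vapply(af, `[`, "", 6L)
  element <- sub("\\..*$", "", type)
  hyb <- ifelse(grepl("\\.", type), sub("^[^.]*\\.", "", type), "other")
  hyb[hyb %in% c("am", "co2", "pl3", "O2", "o2")] <- "2"
  hyb[!(hyb %in% .HYB_LEVELS)] <- "other"
  n_atoms <- length(element)
  if (length(bi) && bi < length(lines)) {
    bl <- lines[(bi + 1L):length(lines)]
    bl <- bl[grepl("^\\s*[0-9]", bl)]
    bf <- strsplit(trimws(bl), "[ \t]+")
    bonds <- data.frame(
      src = vapply(bf, function(x) as.integer(x[2L]), 1L),
      dst = vapply(bf, function(x) as.integer(x[3L]), 1L),
      type = vapply(bf, function(x) if (length(x) >= 4L) x[4L] else "1", "")
    )
  } else {
    bonds <- data.frame(src = integer(0), dst = integer(0), type = character(0))
  }
  charges <- integer(n_atoms)
  toks <- .smiles_atom_tokens(smiles)
  if (length(toks) == n_atoms) charges <- vapply(toks, .formal_charge, 1L, USE.NAMES = FALSE)
  degree <- tabulate(c(bonds$src, bonds$dst), nbins = n_atoms)
  in_ring_bond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0L) {
    g <- igraph::graph_from_edgelist(cbind(bonds$src, bonds$dst), directed = FALSE)
    br <- igraph::bridges(g)
    in_ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  in_ring_atom <- rep(FALSE, n_atoms)
  if (any(in_ring_bond)) {
    ring_atoms <- unique(c(bonds$src[in_ring_bond], bonds$dst[in_ring_bond]))
    in_ring_atom[ring_atoms] <- TRUE
  }
  list(
    element = element, hyb = hyb, charge = charges, degree = degree,
    aromatic = hyb == "ar", bonds = bonds, bond_in_ring = in_ring_bond,
    atom_in_ring = in_ring_atom, n_atoms = n_atoms
  )
}

.one_hot <- function(x, levels) {
  m <- matrix(0, length(x), length(levels))
  idx <- match(x, levels)
  idx[is.na(idx)] <- length(levels)
  m[cbind(seq_along(x), idx)] <- 1
  m
}

#' Convert a SMILES string to a molecular graph
#'
#' Heavy atoms become nodes and chemical bonds become pairs of directed
#' edges. Feature columns follow [atom_feature_schema()].
#'
#' @param smiles A single SMILES string.
#' @return An object of class `molecular_graph` with `node_features`
#'   (n_atoms x d_atom), `edge_index` (n_edges x 2, directed), and
#'   `edge_features` (n_edges x d_bond).
#' @examples
#' g <- smiles_to_graph("CCO")
#' nrow(g$node_features)  # 3 heavy atoms
#' @export
smiles_to_graph <- function(smiles) {
  mol <- .parse_mol(smiles)
  schema <- atom_feature_schema()
  elem <- .one_hot(mol$element, c(.ELEMENTS, "other"))
  elem[mol$element %in% .ELEMENTS == FALSE, length(.ELEMENTS) + 1L] <- 1
  deg <- .one_hot(pmin(pmax(mol$degree, 1L), 5L), as.character(1:5))
  hyb <- .one_hot(mol$hyb, .HYB_LEVELS)
  node_features <- cbind(elem, deg, mol$charge, as.numeric(mol$aromatic), hyb)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    edge_index <- rbind(cbind(b$src, b$dst), cbind(b$dst, b$src))
    btype <- b$type
    btype[!(btype %in% .BOND_LEVELS)] <- "other"
    conj <- (mol$hyb[b$src] %in% c("1", "2", "ar")) & (mol$hyb[b$dst] %in% c("1", "2", "ar"))
    ef1 <- cbind(.one_hot(btype, .BOND_LEVELS), as.numeric(conj), as.numeric(mol$bond_in_ring))
    edge_features <- rbind(ef1, ef1)
  } else {
    edge_index <- matrix(integer(0), 0L, 2L)
    edge_features <- matrix(numeric(0), 0L, schema$d_bond)
  }
  structure(
    list(
      node_features = node_features, edge_index = edge_index,
      edge_features = edge_features, smiles = smiles,
      schema_version = schema$version
    ),
    class = "molecular_graph"
  )
}

# ---- circular fingerprint --------------------------------------------------

# Deterministic order-invariant integer hash (Horner scheme mod 2^31 - 1).
.hash_ints <- function(xs) {
  h <- 7
  for (x in xs) h <- (h * 1000003 + (x %% 2147483647)) %% 2147483647
  h
}

.hash_string <- function(s) .hash_ints(utf8ToInt(s))

# Identifiers of all circular atom environments up to `radius`, ECFP-style:
# start from an atom-invariant hash, then iteratively fold in the sorted
# (bond-order, neighbour-identifier) multiset. Sorting makes the identifier
# independent of atom input order.
.circular_identifiers <- function(mol, radius) {
  bond_code <- match(mol$bonds$type, .BOND_LEVELS)
  bond_code[is.na(bond_code)] <- length(.BOND_LEVELS)
  n <- mol$n_atoms
  nbrs <- vector("list", n)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      s <- mol$bonds$src[k]; d <- mol$bonds$dst[k]; bc <- bond_code[k]
      nbrs[[s]] <- rbind(nbrs[[s]], c(d, bc))
      nbrs[[d]] <- rbind(nbrs[[d]], c(s, bc))
    }
  }
  ids <- vapply(seq_len(n), function(i) {
    .hash_ints(c(
      .hash_string(mol$element[i]), mol$degree[i], mol$charge[i] + 10L,
      as.integer(mol$aromatic[i]), match(mol$hyb[i], .HYB_LEVELS)
    ))
  }, 1)
  all_ids <- ids
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(n), function(i) {
        nb <- nbrs[[i]]
        if (is.null(nb)) return(.hash_ints(c(r, ids[i])))
        pairs <- cbind(nb[, 2L], ids[nb[, 1L]])
        pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
        .hash_ints(c(r, ids[i], as.vector(t(pairs))))
      }, 1)
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  unique(all_ids)
}

#' Compute a circular (Morgan-type) fingerprint
#'
#' Enumerates atom-centred circular substructure environments up to the
#' given radius, hashes each environment to a deterministic identifier, and
#' folds the identifiers into a fixed-length binary vector. The input is
#' canonicalised first, so any valid spelling of the same molecule yields
#' identical bits.
#'
#' @param smiles A single SMILES string.
#' @param L Fingerprint length in bits (default 1024).
#' @param radius Maximum environment radius in bonds (default 2).
#' @return An object of class `fingerprint_vector` with binary `bits`
#'   (length `L`) and the source `smiles`.
#' @examples
#' fp <- compute_fingerprint("CCO")
#' sum(fp$bits)  # number of distinct folded substructure bits
#' @export
compute_fingerprint <- function(smiles, L = 1024L, radius = 2L) {
  stopifnot(L >= 1L, radius >= 0L)
  can <- canonicalize_smiles(smiles)
  mol <- .parse_mol(can)
  ids <- .circular_identifiers(mol, radius)
  bits <- numeric(L)
  bits[(ids %% L) + 1L] <- 1
  structure(list(bits = bits, smiles = smiles, L = L, radius = radius),
            class = "fingerprint_vector")
}

# ---- SMILES tokenizer ------------------------------------------------------

# Character-level with a two-character-element pass: Cl and Br are single
# tokens; every other character is its own token.
.smiles_tokens <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  toks <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (i < length(chars) && paste0(chars[i], chars[i + 1L]) %in% c("Cl", "Br")) {
      toks <- c(toks, paste0(chars[i], chars[i + 1L]))
      i <- i + 2L
    } else {
      toks <- c(toks, chars[i])
      i <- i + 1L
    }
  }
  toks
}

#' Build a SMILES token vocabulary from a training corpus
#'
#' Token id 0 is reserved for padding; the largest id is the
#' unknown-token (UNK) id for characters unseen at training time.
#'
#' @param smiles_vec Character vector of training SMILES.
#' @return An object of class `smiles_vocab`: `token_to_id` (named integer
#'   vector), `unk_id`, `vocab_size`.
#' @export
build_vocab <- function(smiles_vec) {
  toks <- sort(unique(unlist(lapply(smiles_vec, .smiles_tokens))))
  ids <- seq_along(toks)
  names(ids) <- toks
  structure(
    list(token_to_id = ids, unk_id = length(toks) + 1L, vocab_size = length(toks) + 2L),
    class = "smiles_vocab"
  )
}

#' Tokenize a SMILES string to padded integer ids
#'
#' @param smiles A single non-empty SMILES string.
#' @param vocab A [build_vocab()] result.
#' @param max_len Maximum sequence length; longer inputs are truncated with a
#'   warning (dropping them would silently change dataset composition).
#' @return An object of class `token_sequence`: integer `token_ids` and
#'   binary `mask`, both length `max_len`, plus `n_real` and `vocab_size`.
#' @examples
#' v <- build_vocab(c("CCO", "c1ccccc1"))
#' tokenize_smiles("CCO", v, max_len = 5)$token_ids
#' @export
tokenize_smiles <- function(smiles, vocab, max_len = 200L) {
  stopifnot(inherits(vocab, "smiles_vocab"), max_len >= 1L)
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("empty SMILES string cannot be tokenized")
  }
  toks <- .smiles_tokens(smiles)
  ids <- unname(vocab$token_to_id[toks])
  oov <- is.na(ids)
  if (any(oov)) {
    message("tokenize_smiles: ", sum(oov), " out-of-vocabulary token(s) mapped to UNK in '", smiles, "'")
    ids[oov] <- vocab$unk_id
  }
  if (length(ids) > max_len) {
    warning("SMILES longer than max_len (", length(ids), " > ", max_len, "); truncated: '", smiles, "'")
    ids <- ids[seq_len(max_len)]
  }
  n_real <- length(ids)
  token_ids <- c(ids, rep(0L, max_len - n_real))
  structure(
    list(token_ids = as.integer(token_ids),
         mask = as.integer(token_ids != 0L),
         n_real = n_real, vocab_size = vocab$vocab_size),
    class = "token_sequence"
  )
}

#' Reconstruct a SMILES string from a token sequence
#'
#' Inverse of [tokenize_smiles()] for in-vocabulary strings within `max_len`.
#' @param ts A `token_sequence`.
#' @param vocab The vocabulary used to tokenize.
#' @return The reconstructed SMILES string.
#' @export
detokenize_smiles <- function(ts, vocab) {
  stopifnot(inherits(ts, "token_sequence"), inherits(vocab, "smiles_vocab"))
  ids <- ts$token_ids[ts$token_ids != 0L]
  lookup <- names(vocab$token_to_id)[ids]
  lookup[ids == vocab$unk_id] <- "?"
  paste(lookup, collapse = "")
}

#' Write / read a token vocabulary as a plain two-column mapping file
#' @param vocab A `smiles_vocab`.
#' @param path Destination file (token TAB id).
#' @return `path` (write) or a `smiles_vocab` (read).
#' @export
write_vocab <- function(vocab, path) {
  utils::write.table(
    data.frame(token = names(vocab$token_to_id), id = unname(vocab$token_to_id)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = c("character", "integer"))
  ids <- df$id
  names(ids) <- df$token
  structure(
    list(token_to_id = ids, unk_id = length(ids) + 1L, vocab_size = length(ids) + 2L),
    class = "smiles_vocab"
  )
}
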