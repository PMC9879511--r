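# SMILES -> attributed molecular graph.
#
# OpenBabel (via ChemmineOB) does the chemistry: SMILES parsing, kekulized
# bond orders and formal charges (V2000 SDF) and aromaticity perception
# (MOL2 'ar' bonds). Derived atom properties (heavy-atom degree,
# hybridization, implicit valence, radical electrons) and bond conjugation
# are computed here from that connectivity, following RDKit's conventions
# for common organic chemistry.

.ELEMENT_SLOTS <- c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "As",
                    "Se", "Br", "Te", "I", "At")
.HYB_SLOTS <- c("sp", "sp2", "sp3", "sp3d", "sp3d2")
.BONDTYPE_SLOTS <- c("single", "double", "triple", "aromatic")

# allowed valence states per element (smallest state >= bond order sum wins)
.ALLOWED_VALENCE <- list(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5), S = c(2, 4, 6),
  Cl = 1, As = c(3, 5), Se = c(2, 4, 6), Br = 1, Te = c(2, 4, 6), I = 1,
  At = 1, H = 1, Na = 1, K = 1, Li = 1, Mg = 2, Ca = 2, Zn = 2
)

.ob_convert <- function(smiles, to) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", to, paste0(smiles, "\n")),
    error = function(e) stop("invalid SMILES '", smiles, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!nzchar(out)) stop("invalid SMILES '", smiles,
                         "': conversion produced no output", call. = FALSE)
  out
}

.parse_sdf <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na)) stop("unreadable SDF counts line", call. = FALSE)
  element <- character(na)
  charge <- integer(na)
  valence_field <- integer(na)
  radical_hint <- integer(na)
  if (na > 0) for (i in seq_len(na)) {
    tok <- strsplit(trimws(lines[4 + i]), "\\s+")[[1]]
    element[i] <- tok[4]
    code <- suppressWarnings(as.integer(tok[6]))
    charge[i] <- switch(as.character(code), "1" = 3L, "2" = 2L, "3" = 1L,
                        "5" = -1L, "6" = -2L, "7" = -3L, 0L)
    if (!is.na(code) && code == 4L) radical_hint[i] <- 1L  # doublet
    vv <- suppressWarnings(as.integer(tok[10]))
    valence_field[i] <- if (is.na(vv)) 0L else vv
  }
  bi <- integer(nb); bj <- integer(nb); border <- integer(nb)
  if (nb > 0) for (k in seq_len(nb)) {
    l <- lines[4 + na + k]
    bi[k] <- as.integer(substr(l, 1, 3))
    bj[k] <- as.integer(substr(l, 4, 6))
    border[k] <- as.integer(substr(l, 7, 9))
  }
  # property block overrides
  for (l in grep("^M  (CHG|RAD)", lines, value = TRUE)) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    nn <- as.integer(tok[3])
    idx <- as.integer(tok[3 + 2 * seq_len(nn) - 1])
    val <- as.integer(tok[3 + 2 * seq_len(nn)])
    if (tok[2] == "CHG") {
      charge[] <- 0L
      charge[idx] <- val
    } else {
      radical_hint[idx] <- pmax(0L, val - 1L)  # 2=doublet -> 1 electron
    }
  }
  list(n_atoms = na, element = element, charge = charge,
       valence_field = valence_field, radical_hint = radical_hint,
       bond_i = bi, bond_j = bj, bond_order = border)
}

.parse_mol2 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  a0 <- which(lines == "@<TRIPOS>ATOM")
  b0 <- which(lines == "@<TRIPOS>BOND")
  counts <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  na <- as.integer(counts[1]); nb <- as.integer(counts[2])
  sybyl <- character(na)
  if (na > 0) for (i in seq_len(na)) {
    sybyl[i] <- strsplit(trimws(lines[a0 + i]), "\\s+")[[1]][6]
  }
  btype <- character(nb)
  if (nb > 0) for (k in seq_len(nb)) {
    btype[k] <- strsplit(trimws(lines[b0 + k]), "\\s+")[[1]][4]
  }
  list(sybyl = sybyl, bond_type = btype)
}

.smallest_allowed_valence <- function(element, charge, bondsum) {
  base <- .ALLOWED_VALENCE[[element]]
  if (is.null(base)) return(max(bondsum, 0))  # meta elements: no implicit H
  v <- switch(element,
              C = base - abs(charge),
              N = , P = , As = base + charge,
              O = , S = , Se = , Te = base + charge,
              pmax(0, base - abs(charge)))
  v <- v[v >= bondsum]
  if (length(v) == 0) return(bondsum)
  min(v)
}

#' Parse a SMILES string into an attributed molecular graph
#'
#' Converts a SMILES string into a directed-bond molecular graph carrying
#' the atom and bond feature vectors used by the encoder. Hydrogens are
#' implicit (never nodes); every chemical bond contributes two directed
#' bonds; atom ordering follows the SMILES atom order as written (OpenBabel
#' preserves input order). Multi-fragment inputs (salts) are reduced to the
#' largest connected fragment.
#'
#' @param smiles a single non-empty SMILES string.
#' @return An object of class `molecular_graph`: a list with `n_atoms`,
#'   `n_directed_bonds`, `atom_features` (n x 42 matrix),
#'   `bond_features` (m x 6 matrix over directed bonds), `src`, `dst`
#'   (1-based atom indices per directed bond), `reverse_index` (involution
#'   mapping each directed bond to its reverse), `element`, `atoms`
#'   (per-atom descriptor data frame) and `smiles`.
#' @examples
#' g <- parse_smiles("c1ccccc1")   # benzene: 6 atoms, 12 directed bonds
#' g$n_directed_bonds
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("smiles must be a single non-empty string", call. = FALSE)
  sdf <- .parse_sdf(.ob_convert(smiles, "SDF"))
  mol2 <- .parse_mol2(.ob_convert(smiles, "MOL2"))
  if (sdf$n_atoms == 0L)
    stop("degenerate input: '", smiles, "' has no heavy atoms", call. = FALSE)
  if (length(mol2$sybyl) != sdf$n_atoms)
    stop("internal: SDF/MOL2 atom counts disagree for '", smiles, "'",
         call. = FALSE)

  n <- sdf$n_atoms
  bi <- sdf$bond_i; bj <- sdf$bond_j
  order <- sdf$bond_order
  aromatic_bond <- mol2$bond_type == "ar"

  # largest connected fragment (salt stripping)
  if (n > 1L) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = c(bi, seq_len(n)), to = c(bj, seq_len(n))),
      directed = FALSE)
    comp <- igraph::components(g)
    memb <- comp$membership[as.character(seq_len(n))]
    if (comp$no > 1L) {
      keep_c <- which.max(comp$csize)
      keep <- which(memb == keep_c)
      remap <- integer(n); remap[keep] <- seq_along(keep)
      bkeep <- bi %in% keep & bj %in% keep
      bi <- remap[bi[bkeep]]; bj <- remap[bj[bkeep]]
      order <- order[bkeep]
      aromatic_bond <- aromatic_bond[bkeep]
      sdf$element <- sdf$element[keep]
      sdf$charge <- sdf$charge[keep]
      sdf$valence_field <- sdf$valence_field[keep]
      sdf$radical_hint <- sdf$radical_hint[keep]
      mol2$sybyl <- mol2$sybyl[keep]
      n <- length(keep)
    }
  }
  m_undir <- length(bi)

  # ring bonds: any bond that is not a bridge of the molecular graph
  ring_bond <- logical(m_undir)
  if (m_undir > 0) {
    g <- igraph::graph_from_data_frame(data.frame(from = bi, to = bj),
                                       directed = FALSE,
                                       vertices = data.frame(name = seq_len(n)))
    ring_bond[] <- TRUE
    ring_bond[as.integer(igraph::bridges(g))] <- FALSE
  }
  # SYBYL marks acyclic resonance systems (e.g. carboxylates) 'ar' too;
  # chemically aromatic means being part of an aromatic ring
  aromatic_bond <- aromatic_bond & ring_bond

  # per-atom bookkeeping
  degree <- tabulate(c(bi, bj), nbins = n)
  ordv <- ifelse(order == 4L, 1.5, order)  # OB kekulizes; 4 is defensive
  bondsum <- numeric(n)
  for (k in seq_len(m_undir)) {
    bondsum[bi[k]] <- bondsum[bi[k]] + ordv[k]
    bondsum[bj[k]] <- bondsum[bj[k]] + ordv[k]
  }
  bondsum <- ceiling(bondsum)

  allowed <- vapply(seq_len(n), function(i)
    .smallest_allowed_valence(sdf$element[i], sdf$charge[i], bondsum[i]),
    numeric(1))
  implicit_h <- integer(n); radical <- integer(n)
  for (i in seq_len(n)) {
    vv <- sdf$valence_field[i]
    if (vv > 0L) {
      tot <- if (vv == 15L) 0L else vv
      implicit_h[i] <- max(0L, tot - bondsum[i])
      radical[i] <- max(0L, allowed[i] - tot)
    } else {
      implicit_h[i] <- max(0L, allowed[i] - bondsum[i])
      radical[i] <- sdf$radical_hint[i]
    }
  }
  sigma <- degree + implicit_h
  aromatic_atom <- logical(n)
  if (m_undir > 0) {
    aromatic_atom[unique(c(bi[aromatic_bond], bj[aromatic_bond]))] <- TRUE
  }
  has_double <- logical(n); has_triple <- logical(n); n_double <- integer(n)
  for (k in seq_len(m_undir)) {
    if (order[k] == 2L && !aromatic_bond[k]) {
      n_double[bi[k]] <- n_double[bi[k]] + 1L
      n_double[bj[k]] <- n_double[bj[k]] + 1L
      has_double[bi[k]] <- has_double[bj[k]] <- TRUE
    }
    if (order[k] == 3L) has_triple[bi[k]] <- has_triple[bj[k]] <- TRUE
  }

  # conjugation, RDKit-style: pi-capable atoms must not be hypervalent
  atom_pi <- (has_double | has_triple | aromatic_atom) & sigma <= 3
  atom_lp <- sdf$element %in% c("N", "O", "S", "Se", "P") &
    sdf$charge <= 0 & sigma <= 3
  capable <- atom_pi | atom_lp
  conj <- aromatic_bond
  single_conj <- !aromatic_bond & order == 1L &
    capable[bi] & capable[bj]
  conj <- conj | single_conj
  if (m_undir > 0) {
    adj_of <- split(rep(seq_len(m_undir), 2L), c(bi, bj))
    for (k in which(order >= 2L & !aromatic_bond)) {
      for (a in c(bi[k], bj[k])) {
        if (sigma[a] > 3) next
        others <- setdiff(adj_of[[as.character(a)]], k)
        if (any(aromatic_bond[others] | order[others] >= 2L |
                single_conj[others])) {
          conj[k] <- TRUE
          break
        }
      }
    }
  }

  # atom participates in a conjugated single bond through its lone pair
  lp_conj <- logical(n)
  for (k in which(single_conj)) lp_conj[c(bi[k], bj[k])] <- TRUE

  hyb <- character(n)
  for (i in seq_len(n)) {
    hyb[i] <- if (aromatic_atom[i]) "sp2"
    else if ((has_triple[i] || n_double[i] >= 2L) && sigma[i] <= 2L) "sp"
    else if (sigma[i] == 5L) "sp3d"
    else if (sigma[i] == 6L) "sp3d2"
    else if (sigma[i] > 6L) "other"
    else if (has_double[i] && sigma[i] <= 3L) "sp2"
    else if (atom_lp[i] && lp_conj[i] && !has_double[i] && !has_triple[i]) "sp2"
    else "sp3"
  }

  atoms <- data.frame(
    element = sdf$element, degree = degree, hybridization = hyb,
    implicit_valence = implicit_h, radical_electrons = radical,
    formal_charge = sdf$charge, aromatic = as.integer(aromatic_atom),
    stringsAsFactors = FALSE)
  atom_features <- t(vapply(seq_len(n), function(i)
    featurize_atom(atoms[i, ]), numeric(42L)))

  bondtype <- ifelse(aromatic_bond, "aromatic",
                     c("single", "double", "triple")[pmin(order, 3L)])
  bonds <- data.frame(
    i = bi, j = bj, bondtype = bondtype,
    conjugated = as.integer(conj), ring = as.integer(ring_bond),
    stringsAsFactors = FALSE)

  .build_molecular_graph(atom_features, bonds, atoms, smiles)
}

# expand undirected bonds into directed pairs and assemble the object
.build_molecular_graph <- function(atom_features, bonds, atoms, smiles) {
  m_undir <- nrow(bonds)
  if (m_undir > 0) {
    bf_one <- t(vapply(seq_len(m_undir), function(k)
      featurize_bond(bonds[k, ]), numeric(6L)))
    src <- as.vector(rbind(bonds$i, bonds$j))
    dst <- as.vector(rbind(bonds$j, bonds$i))
    bond_features <- bf_one[rep(seq_len(m_undir), each = 2L), , drop = FALSE]
    rev_index <- as.vector(rbind(seq_len(m_undir) * 2L,
                                 seq_len(m_undir) * 2L - 1L))
  } else {
    src <- dst <- rev_index <- integer(0)
    bond_features <- matrix(numeric(0), 0L, 6L)
  }
  structure(list(
    n_atoms = nrow(atom_features),
    n_directed_bonds = 2L * m_undir,
    atom_features = atom_features,
    bond_features = bond_features,
    src = src, dst = dst, reverse_index = rev_index,
    element = atoms$element, atoms = atoms, bonds = bonds,
    smiles = smiles), class = "molecular_graph")
}

#' Build a molecular graph from explicit descriptors
#'
#' Low-level constructor used for toy graphs: takes per-atom and per-bond
#' descriptor rows (as produced by [parse_smiles()]'s `atoms`/`bonds`
#' components) and assembles the directed-bond graph.
#'
#' @param atoms data frame with columns `element`, `degree`,
#'   `hybridization`, `implicit_valence`, `radical_electrons`,
#'   `formal_charge`, `aromatic`.
#' @param bonds data frame with columns `i`, `j`, `bondtype`, `conjugated`,
#'   `ring` (one row per chemical bond).
#' @param smiles optional label.
#' @return A `molecular_graph`.
#' @export
molecular_graph <- function(atoms, bonds, smiles = NA_character_) {
  stopifnot(nrow(atoms) >= 1L)
  if (nrow(bonds) > 0)
    stopifnot(all(bonds$i >= 1), all(bonds$j >= 1),
              all(bonds$i <= nrow(atoms)), all(bonds$j <= nrow(atoms)))
  atom_features <- t(vapply(seq_len(nrow(atoms)), function(i)
    featurize_atom(atoms[i, ]), numeric(42L)))
  .build_molecular_graph(atom_features, bonds, atoms, smiles)
}

#' Featurize one atom (42-dimensional vector)
#'
#' Layout: element one-hot (16 slots, order B, C, N, O, F, Si, P, S, Cl,
#' As, Se, Br, Te, I, At, meta), heavy-atom degree one-hot (11 slots,
#' 0..10), hybridization one-hot (5 slots: sp, sp2, sp3, sp3d, sp3d2;
#' all-zero for states outside this list), implicit valence one-hot
#' (7 slots, 0..6), then integer radical-electron count, integer formal
#' charge and a binary aromaticity flag. Unlisted elements map to the
#' 16th ("meta") slot; degree and implicit valence are clamped to the last
#' slot with a warning.
#'
#' @param atom a one-row data frame (or list) of atom descriptors, see
#'   [molecular_graph()].
#' @return numeric vector of length 42.
#' @export
featurize_atom <- function(atom) {
  el <- rep(0, 16L)
  slot <- match(atom$element, .ELEMENT_SLOTS)
  el[if (is.na(slot)) 16L else slot] <- 1
  deg <- rep(0, 11L)
  d <- atom$degree
  if (d > 10L) {
    warning("atom degree ", d, " clamped to 10")
    d <- 10L
  }
  deg[d + 1L] <- 1
  hyb <- rep(0, 5L)
  hslot <- match(atom$hybridization, .HYB_SLOTS)
  if (!is.na(hslot)) hyb[hslot] <- 1
  else warning("hybridization state '", atom$hybridization,
               "' outside the sp..sp3d2 list; one-hot block left all-zero")
  iv <- rep(0, 7L)
  v <- atom$implicit_valence
  if (v > 6L) {
    warning("implicit valence ", v, " clamped to 6")
    v <- 6L
  }
  iv[v + 1L] <- 1
  c(el, deg, hyb, iv, atom$radical_electrons, atom$formal_charge,
    as.numeric(atom$aromatic))
}

#' Featurize one bond (6-dimensional vector)
#'
#' Layout: bond type one-hot (single, double, triple, aromatic), then a
#' binary conjugation flag and a binary ring-membership flag.
#'
#' @param bond a one-row data frame (or list) with `bondtype`,
#'   `conjugated`, `ring`.
#' @return numeric vector of length 6.
#' @export
featurize_bond <- function(bond) {
  bt <- rep(0, 4L)
  slot <- match(bond$bondtype, .BONDTYPE_SLOTS)
  if (is.na(slot)) stop("unknown bond type '", bond$bondtype, "'")
  bt[slot] <- 1
  c(bt, as.numeric(bond$conjugated), as.numeric(bond$ring))
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph>", if (!is.na(x$smiles)) x$smiles else "", "\n")
  cat("  atoms:", x$n_atoms, " directed bonds:", x$n_directed_bonds, "\n")
  cat("  elements:", paste(x$element, collapse = " "), "\n")
  invisible(x)
}

# serializable summary used by the featurize CLI command and debug dumps
graph_to_list <- function(g) {
  list(smiles = g$smiles, n_atoms = g$n_atoms,
       n_directed_bonds = g$n_directed_bonds,
       element = g$element,
       atom_features = unname(g$atom_features),
       bond_features = unname(g$bond_features),
       src = g$src, dst = g$dst, reverse_index = g$reverse_index)
}
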