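# Synthetic drug/DDI dataset generation with planted motif rules.
#
# Molecules are assembled by concatenating 1-3 fragment SMILES from a
# small library of common functional groups (each fragment is written so
# that its first and last atoms have a free valence, making plain string
# concatenation chemically meaningful most of the time; invalid
# assemblies are resampled). Interactions are planted by rules: a tuple
# (x, y, r) is a positive for rule r when motif_x occurs in drug x and
# motif_y in drug y. Matched motif atoms are recorded per tuple so that
# explanation-recovery experiments can check whether the model's
# attention finds the planted chemistry.

#' Fragment library for synthetic molecule assembly
#'
#' @return character vector of ~30 small fragment SMILES (alkyl chains,
#'   benzene and heteroaromatics, amide, carboxyl, ester, amine, ether,
#'   halides, ...).
#' @export
fragment_library <- function() {
  c("C", "CC", "CCC", "CCCC", "C(C)C", "C(C)(C)C",
    "CCO", "CO", "OC", "CN", "NC", "CCN",
    "C=C", "C=CC", "CC=C",
    "c1ccccc1", "Cc1ccccc1", "c1ccccc1C", "c1ccncc1", "c1ccoc1",
    "C(=O)N", "C(=O)NC", "NC(=O)C",
    "C(=O)O", "C(=O)OC", "OC(=O)C", "C(=O)C",
    "CCl", "C(Cl)C", "CBr", "CS", "CSC")
}

# sampling weights: pharmacophore-like fragments (aromatic rings, amide,
# carboxyl/ester, halide) are favored so planted motifs reach workable
# prevalence in small pools
.fragment_weights <- function(fragments) {
  key <- c("c1ccccc1", "Cc1ccccc1", "c1ccccc1C",
           "C(=O)N", "C(=O)NC", "NC(=O)C",
           "C(=O)O", "C(=O)OC", "OC(=O)C",
           "CCl", "C(Cl)C")
  ifelse(fragments %in% key, 3, 1)
}

# standard-valence sanity: rejects assemblies OpenBabel tolerates but a
# chemist would not (hypervalent halogens, pentavalent carbon, ...)
.valence_sane <- function(graph) {
  caps <- c(C = 4, N = 3, O = 2, S = 6, P = 5, F = 1, Cl = 1, Br = 1,
            I = 1, B = 3, Si = 4)
  ordv <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
  bs <- numeric(graph$n_atoms)
  if (nrow(graph$bonds) > 0) for (k in seq_len(nrow(graph$bonds))) {
    o <- ordv[[graph$bonds$bondtype[k]]]
    bs[graph$bonds$i[k]] <- bs[graph$bonds$i[k]] + o
    bs[graph$bonds$j[k]] <- bs[graph$bonds$j[k]] + o
  }
  bs <- ceiling(bs)
  ok <- TRUE
  for (i in seq_len(graph$n_atoms)) {
    cap <- caps[graph$atoms$element[i]]
    if (!is.na(cap) && bs[i] > cap + abs(graph$atoms$formal_charge[i]))
      ok <- FALSE
  }
  ok
}

.canonical_smiles <- function(smiles) {
  out <- .ob_convert(smiles, "CAN")
  trimws(strsplit(out, "[\t\n]")[[1]][1])
}

#' Generate synthetic drug molecules
#'
#' Assembles `n` unique, valid molecules by joining 1-3 fragments;
#' every emitted SMILES round-trips through [parse_smiles()].
#' Deterministic given `seed`.
#'
#' @param n number of drugs (>= 2).
#' @param seed RNG seed.
#' @param fragments fragment SMILES pool.
#' @param max_tries total resampling bound.
#' @return drug table (`id`, `smiles`) with ids `D001`, `D002`, ...
#' @export
generate_drugs <- function(n, seed = 1L, fragments = fragment_library(),
                           max_tries = 200L * n) {
  stopifnot(n >= 2)
  .with_seed(seed, {
    smiles <- character(0)
    seen <- character(0)
    tries <- 0L
    while (length(smiles) < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not assemble ", n, " unique molecules within ",
             max_tries, " tries", call. = FALSE)
      k <- sample(3L, 1L)
      cand <- paste(sample(fragments, k, replace = TRUE,
                           prob = .fragment_weights(fragments)),
                    collapse = "")
      ok <- tryCatch({
        g <- parse_smiles(cand)
        can <- .canonical_smiles(cand)
        g$n_atoms >= 1 && .valence_sane(g) && !(can %in% seen)
      }, error = function(e) FALSE)
      if (isTRUE(ok)) {
        smiles <- c(smiles, cand)
        seen <- c(seen, .canonical_smiles(cand))
      }
    }
    data.frame(id = sprintf("D%03d", seq_len(n)), smiles = smiles,
               stringsAsFactors = FALSE)
  })
}

#' Planted motif rule
#'
#' A rule states that drugs containing `motif_x` interact with drugs
#' containing `motif_y` under interaction type `relation`. Motifs are
#' fragment patterns written as SMILES and matched as labeled subgraphs
#' (element + aromaticity on atoms, bond order class on bonds).
#'
#' @param motif_x,motif_y pattern SMILES.
#' @param relation interaction type id (0-based).
#' @param noise_rate probability of flipping a positive's label
#'   (0 <= rate < 0.5).
#' @return list of class `motif_rule`.
#' @export
motif_rule <- function(motif_x, motif_y, relation, noise_rate = 0.05) {
  stopifnot(noise_rate >= 0, noise_rate < 0.5)
  parse_smiles(motif_x)  # patterns must parse
  parse_smiles(motif_y)
  structure(list(motif_x = motif_x, motif_y = motif_y,
                 relation = as.integer(relation),
                 noise_rate = noise_rate), class = "motif_rule")
}

#' Default pair of motif rules
#'
#' Type 0: amide-bearing drugs interact with benzene-bearing drugs;
#' type 1: carboxyl/ester-bearing drugs interact with chlorinated drugs.
#' Single functional groups, so a 3-layer receptive field covers them.
#'
#' @param noise_rate label-flip probability shared by both rules.
#' @export
default_motif_rules <- function(noise_rate = 0.05) {
  list(motif_rule("C(=O)N", "c1ccccc1", 0L, noise_rate),
       motif_rule("C(=O)O", "Cl", 1L, noise_rate))
}

.mol_to_igraph <- function(g) {
  el <- match(g$atoms$element, .ELEMENT_SLOTS)
  el[is.na(el)] <- 16L
  vcol <- el * 2L + g$atoms$aromatic
  if (nrow(g$bonds) > 0) {
    ig <- igraph::graph_from_data_frame(
      g$bonds[, c("i", "j")], directed = FALSE,
      vertices = data.frame(name = seq_len(g$n_atoms)))
    igraph::E(ig)$color <- match(g$bonds$bondtype, .BONDTYPE_SLOTS)
  } else {
    ig <- igraph::make_empty_graph(n = g$n_atoms, directed = FALSE)
  }
  igraph::V(ig)$color <- vcol
  ig
}

#' Find motif occurrences in a molecule
#'
#' Labeled subgraph isomorphism (VF2): atoms must agree on element and
#' aromaticity, bonds on bond-type class. Matches are deduplicated by
#' atom set and returned in lexicographic order.
#'
#' @param pattern motif pattern (SMILES string or `molecular_graph`).
#' @param graph target `molecular_graph`.
#' @return list of integer vectors (sorted atom indices per occurrence);
#'   empty list if the motif is absent.
#' @export
match_motif <- function(pattern, graph) {
  pg <- if (inherits(pattern, "molecular_graph")) pattern
        else parse_smiles(pattern)
  if (pg$n_atoms > graph$n_atoms) return(list())
  # edgeless patterns (single atoms) carry no edge colors; igraph then
  # ignores edge colors with a warning that is irrelevant for 0 edges
  maps <- suppressWarnings(
    igraph::subgraph_isomorphisms(.mol_to_igraph(pg),
                                  .mol_to_igraph(graph),
                                  method = "vf2"))
  sets <- unique(lapply(maps, function(m) sort(as.integer(m))))
  sets[order(vapply(sets, paste, character(1), collapse = ","))]
}

#' Generate a DDI dataset from drugs and motif rules
#'
#' Positives are sampled uniformly from the drug pairs satisfying each
#' rule (motif_x in drug x, motif_y in drug y, x != y), with tuples
#' allocated as evenly as possible across rules and deduplicated. Labels
#' start at 1 and are flipped with the rule's `noise_rate` (structures
#' are never perturbed). The matched motif atoms of both drugs are
#' recorded per tuple.
#'
#' @param drugs drug table (`id`, `smiles`).
#' @param rules list of [motif_rule()]s.
#' @param n_tuples number of positive tuples to emit.
#' @param seed RNG seed.
#' @param graphs optional pre-parsed graphs (named by drug id).
#' @param min_coverage minimum fraction of drugs containing each motif.
#' @param neg_ratio rule-violating negatives per positive (label 0,
#'   pairs where the rule's motif pair does NOT hold; 0 disables them —
#'   corruption sampling via [negative_sampling()] is then the way to
#'   obtain label-0 tuples).
#' @return list of class `synthetic_ddi_dataset` with `drugs`, `tuples`
#'   (`drug_x`, `drug_y`, `type`, `label`), `truth` (per-tuple planted
#'   motif atoms and rule; negatives carry no atoms), and `provenance`.
#' @export
generate_ddi_dataset <- function(drugs, rules = default_motif_rules(),
                                 n_tuples = 100L, seed = 1L,
                                 graphs = NULL, min_coverage = 0.10,
                                 neg_ratio = 1) {
  stopifnot(length(rules) >= 1)
  if (is.null(graphs)) graphs <- parse_drug_table(drugs)
  match_x <- lapply(rules, function(r)
    lapply(graphs, function(g) match_motif(r$motif_x, g)))
  match_y <- lapply(rules, function(r)
    lapply(graphs, function(g) match_motif(r$motif_y, g)))
  for (k in seq_along(rules)) {
    cov_x <- mean(lengths(match_x[[k]]) > 0)
    cov_y <- mean(lengths(match_y[[k]]) > 0)
    if (cov_x < min_coverage || cov_y < min_coverage)
      stop("rule ", k, " motifs cover too few drugs (",
           round(100 * cov_x), "% / ", round(100 * cov_y),
           "%); regenerate drugs or relax the rules", call. = FALSE)
  }
  alloc <- rep(n_tuples %/% length(rules), length(rules))
  rem <- n_tuples %% length(rules)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  .with_seed(seed, {
    rows <- list()
    truth <- list()
    seen <- character(0)
    for (k in seq_along(rules)) {
      rule <- rules[[k]]
      cx <- drugs$id[lengths(match_x[[k]]) > 0]
      cy <- drugs$id[lengths(match_y[[k]]) > 0]
      got <- 0L
      tries <- 0L
      max_tries <- 200L * max(1L, alloc[k])
      while (got < alloc[k]) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("rule ", k, ": could not sample ", alloc[k],
               " distinct tuples (pool too small)", call. = FALSE)
        x <- sample(cx, 1L)
        y <- sample(cy, 1L)
        if (x == y) next
        kk <- paste(x, y, rule$relation, sep = "\r")
        if (kk %in% seen) next
        seen <- c(seen, kk)
        got <- got + 1L
        label <- if (stats::runif(1) < rule$noise_rate) 0L else 1L
        rows[[length(rows) + 1L]] <- data.frame(
          drug_x = x, drug_y = y, type = rule$relation, label = label,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- list(
          rule = k, atoms_x = match_x[[k]][[x]][[1L]],
          atoms_y = match_y[[k]][[y]][[1L]])
      }
      n_neg <- round(neg_ratio * alloc[k])
      got <- 0L
      tries <- 0L
      max_tries <- 500L * max(1L, n_neg)
      while (got < n_neg) {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("rule ", k, ": could not sample ", n_neg,
               " rule-violating negatives", call. = FALSE)
        x <- sample(drugs$id, 1L)
        y <- sample(drugs$id, 1L)
        if (x == y) next
        if (length(match_x[[k]][[x]]) > 0 &&
            length(match_y[[k]][[y]]) > 0) next   # satisfies the rule
        kk <- paste(x, y, rule$relation, sep = "\r")
        if (kk %in% seen) next
        seen <- c(seen, kk)
        got <- got + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          drug_x = x, drug_y = y, type = rule$relation, label = 0L,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- list(
          rule = k, atoms_x = NULL, atoms_y = NULL)
      }
    }
    tuples <- if (length(rows) == 0)
      data.frame(drug_x = character(0), drug_y = character(0),
                 type = integer(0), label = integer(0),
                 stringsAsFactors = FALSE)
    else do.call(rbind, rows)
    rownames(tuples) <- NULL
    structure(list(
      drugs = drugs, tuples = tuples, truth = truth, graphs = graphs,
      provenance = list(
        seed = seed, n_tuples = n_tuples, neg_ratio = neg_ratio,
        allocation = alloc,
        rules = lapply(rules, unclass),
        generated = "ddinet synthetic generator")),
      class = "synthetic_ddi_dataset")
  })
}

#' Random DDI tuples without planted structure
#'
#' Uniformly samples distinct (drug_x, drug_y, type) tuples with label 1;
#' useful for capacity/memorization experiments where no chemistry is
#' supposed to explain the labels.
#'
#' @param drugs drug table.
#' @param n number of tuples.
#' @param n_relations number of interaction types.
#' @param seed RNG seed.
#' @return data frame of labeled tuples.
#' @export
random_ddi_tuples <- function(drugs, n, n_relations = 2L, seed = 1L) {
  ids <- drugs$id
  stopifnot(length(ids) >= 2)
  pool <- expand.grid(drug_x = ids, drug_y = ids,
                      type = seq_len(n_relations) - 1L,
                      stringsAsFactors = FALSE)
  pool <- pool[pool$drug_x != pool$drug_y, ]
  if (n > nrow(pool))
    stop("only ", nrow(pool), " distinct tuples possible", call. = FALSE)
  out <- .with_seed(seed, pool[sample.int(nrow(pool), n), ])
  out$label <- 1L
  rownames(out) <- NULL
  out
}

#' One-call synthetic dataset
#'
#' Generates drugs (resampling with derived seeds until every motif
#' reaches the coverage floor) and then the tuple set.
#'
#' @param n_drugs,n_tuples dataset size.
#' @param rules motif rules.
#' @param seed master seed.
#' @param max_attempts drug-pool resampling bound.
#' @inheritParams generate_ddi_dataset
#' @export
generate_synthetic_dataset <- function(n_drugs = 60L, n_tuples = 400L,
                                       rules = default_motif_rules(),
                                       seed = 1L, min_coverage = 0.10,
                                       max_attempts = 20L, neg_ratio = 1) {
  for (a in seq_len(max_attempts)) {
    drugs <- generate_drugs(n_drugs, seed = seed + 1000L * (a - 1L))
    ds <- tryCatch(
      generate_ddi_dataset(drugs, rules, n_tuples, seed = seed,
                           min_coverage = min_coverage,
                           neg_ratio = neg_ratio),
      error = function(e) e)
    if (!inherits(ds, "error")) return(ds)
  }
  stop("no drug pool met the motif coverage floor after ",
       max_attempts, " attempts: ", conditionMessage(ds), call. = FALSE)
}

#' Write a synthetic dataset to disk
#'
#' Emits `drugs.csv`, `ddis.csv` (the dialects [read_drug_table()] and
#' [read_ddi_table()] read) and a `provenance.json` sidecar including
#' the per-tuple planted motif atoms.
#'
#' @param dataset a `synthetic_ddi_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_drug_table(dataset$drugs, file.path(dir, "drugs.csv"))
  write_ddi_table(dataset$tuples, file.path(dir, "ddis.csv"))
  jsonlite::write_json(
    list(provenance = dataset$provenance, truth = dataset$truth),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
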