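## Molecular-graph construction as the baseline models consume it: nodes are
## retained heavy atoms, edges join every atom pair within a radius cutoff
## (4.5 A), and each edge is weighted by the inverse of its length.

.default_vocab <- c("C", "N", "O", "S", "P", "F", "CL", "BR", "I")

## all pairs within cutoff: returns list(edges = 2-col matrix i<j, dist)
.radius_edges <- function(xyz, cutoff) {
  n <- nrow(xyz)
  ei <- NULL
  for (i in seq_len(max(n - 1L, 0L))) {
    d <- sweep(xyz[(i + 1L):n, , drop = FALSE], 2, xyz[i, ])
    dist <- sqrt(rowSums(d * d))
    hits <- which(dist <= cutoff)
    if (length(hits))
      ei <- rbind(ei, cbind(i, i + hits, dist[hits]))
  }
  if (is.null(ei))
    list(edges = matrix(integer(), ncol = 2), dist = numeric())
  else
    list(edges = cbind(as.integer(ei[, 1]), as.integer(ei[, 2])),
         dist = unname(ei[, 3]))
}

#' Build a molecular graph from a complex
#'
#' Nodes are the retained atoms (hydrogens, waters and ions dropped by
#' default); an undirected edge joins every atom pair within `cutoff`
#' Angstrom, weighted by the inverse distance (1/d, 1/Angstrom). Node
#' features start with a one-hot element block over `vocab` plus an "other"
#' bucket; extra per-atom feature blocks are appended in declared order, each
#' followed by a 0/1 mask column (absent values are 0-filled with mask 0).
#'
#' @param complex a [complex_record()], or a bare atom `data.frame` (e.g. an
#'   isolated ligand molecule).
#' @param cutoff edge radius, Angstrom (default 4.5).
#' @param drop_hydrogens exclude hydrogens (default `TRUE`).
#' @param extra_node_features named list of per-complex-atom numeric vectors
#'   (e.g. `charge`, `adaptability`); `NA` entries are masked.
#' @param vocab one-hot element vocabulary (an `other` bucket is appended).
#' @param subset optional atom indices to retain (e.g. a pocket selection)
#'   applied before hydrogen/role filtering.
#' @return object of class `mol_graph`: `node_features` (n x f matrix),
#'   `node_origin` (`protein`/`ligand`), `coordinates` (n x 3),
#'   `edges` (m x 2, i < j), `edge_weights` (1/Angstrom), `atom_indices`
#'   (node -> complex atom), `feature_blocks`.
#' @export
build_graph <- function(complex, cutoff = 4.5, drop_hydrogens = TRUE,
                        extra_node_features = list(),
                        vocab = .default_vocab, subset = NULL) {
  at <- if (is.data.frame(complex)) complex else complex$atoms
  keep <- if (is.null(subset)) seq_len(nrow(at)) else sort(unique(subset))
  keep <- keep[at$role[keep] %in% c("protein", "ligand")]
  if (drop_hydrogens) keep <- keep[at$element[keep] != "H"]
  if (length(keep) < 2L)
    stop_ligdyn("validation", "graph needs >= 2 retained atoms, got %d",
                length(keep))
  el <- at$element[keep]
  vocab <- .norm_element(vocab)
  slot <- match(el, vocab)
  slot[is.na(slot)] <- length(vocab) + 1L
  onehot <- matrix(0, length(keep), length(vocab) + 1L,
                   dimnames = list(NULL, c(vocab, "other")))
  onehot[cbind(seq_along(slot), slot)] <- 1
  feats <- onehot
  blocks <- list(onehot = colnames(onehot))
  for (nm in names(extra_node_features)) {
    v <- extra_node_features[[nm]]
    if (length(v) != nrow(at))
      stop_ligdyn("validation",
                  "extra feature '%s' has length %d, complex has %d atoms",
                  nm, length(v), nrow(at))
    v <- v[keep]
    mask <- as.numeric(!is.na(v))
    v[is.na(v)] <- 0
    add <- cbind(v, mask)
    colnames(add) <- c(nm, paste0(nm, "_mask"))
    feats <- cbind(feats, add)
    blocks[[nm]] <- colnames(add)
  }
  xyz <- as.matrix(at[keep, c("x", "y", "z")])
  re <- .radius_edges(xyz, cutoff)
  structure(list(node_features = feats,
                 node_origin = at$role[keep],
                 coordinates = xyz,
                 edges = re$edges,
                 edge_weights = 1 / re$dist,
                 atom_indices = keep,
                 feature_blocks = blocks,
                 cutoff = cutoff),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph: %d nodes, %d edges, %d features [%s]>\n",
              nrow(x$node_features), nrow(x$edges), ncol(x$node_features),
              paste(names(x$feature_blocks), collapse = "+")))
  invisible(x)
}

#' Select binding-pocket atoms
#'
#' Returns the indices of all protein atoms belonging to residues that have
#' any heavy atom within `pocket_cutoff` of any ligand heavy atom, plus all
#' ligand atoms. Residues enter or leave atomically (whole residues).
#'
#' @param complex a [complex_record()].
#' @param pocket_cutoff Angstrom (default 8).
#' @return sorted integer index set into the complex atom table.
#' @export
select_pocket <- function(complex, pocket_cutoff = 8.0) {
  at <- complex$atoms
  heavy <- .is_heavy(at)
  lig_h <- intersect(complex$ligand_indices, which(heavy))
  prot_h <- intersect(complex$protein_indices, which(heavy))
  if (length(lig_h) == 0L)
    stop_ligdyn("validation", "no heavy ligand atoms")
  lx <- as.matrix(at[lig_h, c("x", "y", "z")])
  near <- vapply(prot_h, function(i) {
    d <- sweep(lx, 2, as.numeric(at[i, c("x", "y", "z")]))
    min(rowSums(d * d)) <= pocket_cutoff^2
  }, logical(1))
  res_key <- paste(at$chain_id, at$residue_index)
  hit_res <- unique(res_key[prot_h[near]])
  prot_sel <- intersect(complex$protein_indices,
                        which(res_key %in% hit_res))
  sort(union(prot_sel, complex$ligand_indices))
}

#' Filter regression targets by a wide standard-deviation band
#'
#' Single-pass outlier removal used before model training: entries whose
#' value strays more than `k_sd` standard deviations from the mean (both
#' computed once over all entries) are dropped. The default of 20 s.d. only
#' removes pathological target values. A zero standard deviation retains
#' everything.
#'
#' @param values per-entry numeric vector.
#' @param k_sd band half-width in standard deviations (default 20).
#' @return integer indices of the retained entries.
#' @export
filter_target_outliers <- function(values, k_sd = 20) {
  if (length(values) < 2L)
    stop_ligdyn("validation", "need >= 2 entries")
  m <- mean(values); s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(seq_along(values))
  which(abs(values - m) <= k_sd * s)
}

#' Random node-translation augmentation
#'
#' Training-time augmentation: each node's coordinates are independently
#' perturbed, per axis, uniformly in `[-amplitude, +amplitude]` (default
#' 0.05 Angstrom); edges and inverse-distance weights are recomputed from
#' the perturbed coordinates. Deterministic for a fixed seed.
#'
#' @param graph a [build_graph()] result.
#' @param amplitude Angstrom (default 0.05).
#' @param seed integer RNG seed.
#' @param distribution `"uniform"` (default) or `"gaussian"` (s.d. =
#'   `amplitude`).
#' @return a perturbed `mol_graph`.
#' @export
augment_translate <- function(graph, amplitude = 0.05, seed = 1L,
                              distribution = c("uniform", "gaussian")) {
  distribution <- match.arg(distribution)
  if (amplitude < 0) stop_ligdyn("validation", "amplitude must be >= 0")
  if (amplitude == 0) return(graph)
  n <- nrow(graph$coordinates)
  noise <- withr::with_seed(seed, {
    if (distribution == "uniform")
      matrix(stats::runif(3 * n, -amplitude, amplitude), n, 3)
    else
      matrix(stats::rnorm(3 * n, 0, amplitude), n, 3)
  })
  xyz <- graph$coordinates + noise
  re <- .radius_edges(xyz, graph$cutoff)
  graph$coordinates <- xyz
  graph$edges <- re$edges
  graph$edge_weights <- 1 / re$dist
  graph
}

#' Build target/base pairs for relative-affinity learning
#'
#' Groups affinity records into clusters sharing protein group and affinity
#' type, discards singleton clusters, designates the cluster-median-affinity
#' entry as the base molecule (ties broken by lexicographically smallest
#' entry id) and pairs it with every other member. The label is the decimal
#' log ratio `log10(affinity_target / affinity_base)`, so swapping target
#' and base negates it and equal affinities give 0. The base is not paired
#' with itself unless `include_self = TRUE`.
#'
#' @param records an [affinity_table()].
#' @param graphs optional named list of [build_graph()] objects keyed by
#'   entry id, attached to the pairs.
#' @param include_self also emit the base-base pair with label 0.
#' @return list of `pair_sample` objects: `target_id`, `base_id`, `label`,
#'   `cluster_id`, and `target_graph`/`base_graph` when supplied.
#' @export
make_pairs <- function(records, graphs = NULL, include_self = FALSE) {
  cl <- paste(records$protein_group, records$affinity_type, sep = "|")
  pairs <- list()
  for (g in sort(unique(cl))) {
    idx <- which(cl == g)
    if (length(idx) < 2L) next                      # singleton cluster: discarded
    ord <- idx[order(records$affinity_value[idx], records$entry_id[idx])]
    base <- ord[ceiling(length(ord) / 2)]           # median affinity
    others <- if (include_self) idx else setdiff(idx, base)
    for (t in others) {
      p <- list(target_id = records$entry_id[t],
                base_id = records$entry_id[base],
                label = log10(records$affinity_value[t] /
                              records$affinity_value[base]),
                cluster_id = g)
      if (!is.null(graphs)) {
        p$target_graph <- graphs[[p$target_id]]
        p$base_graph <- graphs[[p$base_id]]
      }
      pairs[[length(pairs) + 1L]] <- structure(p, class = "pair_sample")
    }
  }
  pairs
}
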