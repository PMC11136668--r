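## Benchmark-set construction, leakage-aware splitting by sequence
## clustering, and the B-factor / RMSF experimental-validation procedure.

#' Build affinity benchmark sets
#'
#' Groups affinity records by (publication, protein group, affinity type)
#' and keeps groups that (i) have at least `min_entries` members, (ii) span
#' at least `min_dynamic_range` decades of affinity (log10 max/min),
#' (iii) whose protein group occurs at most `max_cooccurrence` times outside
#' the group, and (iv), when `exclude_site_cofactors`, contain no member
#' flagged with a cofactor or metal at the binding site. Output is
#' independent of input row order.
#'
#' @param records an [affinity_table()].
#' @param min_entries minimum group size (default 15).
#' @param min_dynamic_range decades of affinity (default 2).
#' @param max_cooccurrence maximum occurrences of the protein group outside
#'   the candidate set (default 5).
#' @param exclude_site_cofactors drop groups with flagged members (default
#'   `TRUE`).
#' @return list of `benchmark_set` objects: `name`, `members` (subset of the
#'   table), `dynamic_range` (log10 units).
#' @export
build_benchmark <- function(records, min_entries = 15,
                            min_dynamic_range = 2.0, max_cooccurrence = 5,
                            exclude_site_cofactors = TRUE) {
  key <- paste(records$publication_id, records$protein_group,
               records$affinity_type, sep = "|")
  sets <- list()
  for (g in sort(unique(key))) {
    idx <- which(key == g)
    if (length(idx) < min_entries) next
    aff <- records$affinity_value[idx]
    dr <- log10(max(aff) / min(aff))
    if (dr < min_dynamic_range) next
    pg <- records$protein_group[idx[1]]
    outside <- sum(records$protein_group == pg) - length(idx)
    if (outside > max_cooccurrence) next
    if (exclude_site_cofactors &&
        any(records$has_site_cofactor_or_metal[idx])) next
    members <- records[idx, , drop = FALSE]
    rownames(members) <- NULL
    sets[[length(sets) + 1L]] <-
      structure(list(name = g, members = members, dynamic_range = dr),
                class = "benchmark_set")
  }
  sets
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat(sprintf("<benchmark_set %s: %d entries, %.2f log10 range>\n",
              x$name, nrow(x$members), x$dynamic_range))
  invisible(x)
}

## ------------------------------------------------- sequence splitting

## 3-mer containment identity between two sequences (set semantics)
.kmer_set <- function(seq, k = 3L) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Pairwise k-mer containment identity
#'
#' `|kmers(a) ∩ kmers(b)| / min(|kmers(a)|, |kmers(b)|)` over unique
#' k-mers (k = 3): an alignment-free stand-in for sequence identity with the
#' same threshold semantics.
#'
#' @param a,b amino-acid sequences (strings).
#' @param k k-mer length (default 3).
#' @return identity fraction in [0, 1].
#' @export
kmer_identity <- function(a, b, k = 3L) {
  sa <- .kmer_set(a, k); sb <- .kmer_set(b, k)
  length(intersect(sa, sb)) / min(length(sa), length(sb))
}

#' Leakage-aware split by sequence clustering
#'
#' Single-linkage clusters of the protein sequences at `similarity_threshold`
#' k-mer containment identity are assigned whole to train/validation/test by
#' a seeded greedy bin-packing toward the target fractions (largest cluster
#' first, ties shuffled by the seed; each cluster goes to the split with the
#' largest remaining deficit). No pair of entries in different splits can
#' reach the identity threshold, by construction of single linkage.
#'
#' @param entry_id entry keys.
#' @param sequences amino-acid sequences, same length as `entry_id`.
#' @param fractions target train/validation/test fractions, summing to 1
#'   (default `c(0.8, 0.1, 0.1)`).
#' @param similarity_threshold identity at or above which two sequences must
#'   share a split (default 0.3).
#' @param seed RNG seed; the same seed reproduces the split exactly.
#' @return data.frame of class `split_assignment`: `entry_id`, `cluster_id`,
#'   `split`.
#' @export
split_by_sequence <- function(entry_id, sequences,
                              fractions = c(0.8, 0.1, 0.1),
                              similarity_threshold = 0.3, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L)
    stop_ligdyn("validation", "fractions must be 3 values summing to 1")
  n <- length(entry_id)
  stopifnot(length(sequences) == n)
  if (any(!nzchar(sequences)))
    stop_ligdyn("validation", "empty sequence(s)")
  ksets <- lapply(sequences, .kmer_set)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      if (j > n) break
      id <- length(intersect(ksets[[i]], ksets[[j]])) /
        min(length(ksets[[i]]), length(ksets[[j]]))
      if (id >= similarity_threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  cluster_id <- match(root, unique(root))
  ## seeded greedy bin-packing of whole clusters
  sizes <- table(cluster_id)
  cl <- as.integer(names(sizes))
  set.seed(seed)
  ord <- cl[order(-as.integer(sizes), sample.int(length(cl)))]
  splits <- c("train", "validation", "test")
  assigned <- setNames(numeric(3), splits)
  cl_split <- character(max(cluster_id))
  for (cc in ord) {
    deficit <- fractions * n - assigned
    pick <- splits[which.max(deficit)]
    cl_split[cc] <- pick
    assigned[pick] <- assigned[pick] + sizes[as.character(cc)]
  }
  out <- data.frame(entry_id = as.character(entry_id),
                    cluster_id = cluster_id,
                    split = cl_split[cluster_id],
                    stringsAsFactors = FALSE)
  class(out) <- c("split_assignment", "data.frame")
  out
}

## ------------------------------------------- B-factor / RMSF validation

#' Correlate experimental B factors with simulated RMSF
#'
#' For each complex/trajectory pair: entries whose modal B-factor value
#' accounts for at least `modal_fraction` of atoms are omitted (placeholder
#' B columns), remaining entries with fewer than 3 usable atoms are skipped,
#' and for the rest the Pearson correlation between per-atom B factor and
#' RMSF (after superposition to the first frame) is computed over heavy
#' atoms with a B factor present.
#'
#' @param complexes list of [complex_record()] with B factors.
#' @param trajectories list of matching [trajectory_record()].
#' @param modal_fraction omission threshold (default 0.8, boundary
#'   inclusive).
#' @return list with `per_entry` (data.frame: `entry_id`, `correlation`,
#'   `status`) and `mean_correlation` over the retained entries.
#' @export
bfactor_rmsf_validation <- function(complexes, trajectories,
                                    modal_fraction = 0.8) {
  stopifnot(length(complexes) == length(trajectories))
  rows <- list()
  for (i in seq_along(complexes)) {
    cx <- complexes[[i]]; tr <- trajectories[[i]]
    b <- cx$atoms$b_factor
    keep <- which(.is_heavy(cx$atoms) & !is.na(b))
    status <- "ok"; r <- NA_real_
    if (length(keep) == 0L) {
      status <- "no_b_factors"
    } else {
      tab <- table(b[keep])
      if (max(tab) / length(keep) >= modal_fraction) {
        status <- "omitted_modal_b"
      } else if (length(keep) < 3L) {
        status <- "too_few_atoms"
      } else {
        fl <- rmsf(tr, cx)
        r <- stats::cor(b[keep], fl[keep])
      }
    }
    rows[[i]] <- data.frame(entry_id = cx$entry_id, correlation = r,
                            status = status, stringsAsFactors = FALSE)
  }
  per_entry <- do.call(rbind, rows)
  list(per_entry = per_entry,
       mean_correlation = mean(per_entry$correlation[per_entry$status == "ok"]))
}
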