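## fixture: four candidate publication groups, exactly two of which pass
## every benchmark filter
benchmark_fixture <- function() {
  mk <- function(n, pub, prot, lo, hi, cof = FALSE) {
    affinity_table(sprintf("%s%03d", pub, seq_len(n)),
                   10^seq(lo, hi, length.out = n), "Ki", prot, pub, cof)
  }
  good1 <- mk(16, "GA", "UP01", 0, 3)       # passes everything
  good2 <- mk(20, "GB", "UP02", 1, 4)       # passes everything
  small <- mk(14, "SM", "UP03", 0, 3)       # one entry short
  narrow <- mk(16, "NR", "UP04", 1, 2)      # 1 decade only
  tab <- rbind(good1, good2, small, narrow)
  class(tab) <- c("affinity_table", "data.frame")
  tab
}

test_that("benchmark filters keep exactly the planted passing groups", {
  tab <- benchmark_fixture()
  sets <- build_benchmark(tab)
  expect_length(sets, 2L)
  expect_setequal(vapply(sets, function(s) s$members$publication_id[1], ""),
                  c("GA", "GB"))
  ## the 14-entry group is rejected by min_entries alone
  small_only <- tab[tab$publication_id == "SM", ]
  class(small_only) <- c("affinity_table", "data.frame")
  expect_length(build_benchmark(small_only), 0L)
  ## a 10-fold (1 decade) range fails the 2-decade default
  narrow_only <- tab[tab$publication_id == "NR", ]
  class(narrow_only) <- c("affinity_table", "data.frame")
  expect_length(build_benchmark(narrow_only), 0L)
  expect_length(build_benchmark(narrow_only, min_dynamic_range = 0.5), 1L)
})

test_that("cofactor and co-occurrence rules remove offending groups", {
  tab <- benchmark_fixture()
  tab$has_site_cofactor_or_metal[tab$publication_id == "GA"] <- TRUE
  sets <- build_benchmark(tab)
  expect_equal(vapply(sets, function(s) s$members$publication_id[1], ""), "GB")
  sets2 <- build_benchmark(tab, exclude_site_cofactors = FALSE)
  expect_length(sets2, 2L)

  ## protein occurring often outside its candidate set
  extra <- affinity_table(sprintf("X%03d", 1:8), rep(100, 8), "Kd", "UP02",
                          "other_pub")
  tab3 <- rbind(benchmark_fixture(), extra)
  class(tab3) <- c("affinity_table", "data.frame")
  sets3 <- build_benchmark(tab3)
  expect_false("UP02" %in%
                 vapply(sets3, function(s) s$members$protein_group[1], ""))
})

test_that("benchmark output is independent of record order", {
  tab <- benchmark_fixture()
  set.seed(50)
  shuf <- tab[sample(nrow(tab)), ]
  class(shuf) <- c("affinity_table", "data.frame")
  a <- build_benchmark(tab); b <- build_benchmark(shuf)
  expect_equal(vapply(a, function(s) s$name, ""),
               vapply(b, function(s) s$name, ""))
  expect_equal(lapply(a, function(s) sort(s$members$entry_id)),
               lapply(b, function(s) sort(s$members$entry_id)))
})

## random-but-related sequence families for split tests
make_families <- function(seed, n_fam, members_per_fam, len = 90) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- character(); ids <- character()
  for (f in seq_len(n_fam)) {
    anc <- sample(aa, len, TRUE)
    for (m in seq_len(members_per_fam)) {
      s <- anc
      mut <- sample(len, round(0.1 * len))
      s[mut] <- sample(aa, length(mut), TRUE)
      seqs <- c(seqs, paste(s, collapse = ""))
      ids <- c(ids, sprintf("F%02dM%02d", f, m))
    }
  }
  data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
}

test_that("identical sequences share a cluster and a split", {
  fam <- make_families(51, 3, 2)
  dup <- rbind(fam, data.frame(id = "DUP01", seq = fam$seq[1]))
  sp <- split_by_sequence(dup$id, dup$seq, seed = 2)
  expect_equal(sp$cluster_id[sp$entry_id == "DUP01"],
               sp$cluster_id[sp$entry_id == fam$id[1]])
  expect_equal(sp$split[sp$entry_id == "DUP01"],
               sp$split[sp$entry_id == fam$id[1]])
})

test_that("splits respect cluster atomicity, target fractions and the seed", {
  fam <- make_families(52, 10, 4)
  sp <- split_by_sequence(fam$id, fam$seq, seed = 7)
  ## clusters never straddle splits
  for (cc in unique(sp$cluster_id))
    expect_length(unique(sp$split[sp$cluster_id == cc]), 1L)
  ## achieved fractions within one cluster's mass of the targets
  n <- nrow(sp)
  max_cluster <- max(table(sp$cluster_id))
  frac <- table(factor(sp$split, c("train", "validation", "test"))) / n
  expect_lt(abs(frac[["train"]] - 0.8), max_cluster / n + 1e-9)
  expect_lt(abs(frac[["validation"]] - 0.1), max_cluster / n + 1e-9)
  expect_lt(abs(frac[["test"]] - 0.1), max_cluster / n + 1e-9)
  ## determinism
  expect_identical(sp, split_by_sequence(fam$id, fam$seq, seed = 7))
  expect_error(split_by_sequence(fam$id, fam$seq, fractions = c(0.5, 0.5)),
               "fractions", class = "ligdyn_validation_error")
})

test_that("no cross-split pair reaches the identity threshold", {
  fam <- make_families(53, 8, 3)
  sp <- split_by_sequence(fam$id, fam$seq, seed = 9)
  n <- nrow(fam)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sp$split[i] != sp$split[j])
      expect_lt(kmer_identity(fam$seq[i], fam$seq[j]), 0.3)
  }
})

test_that("B-factor/RMSF validation respects affine scaling and cleaning", {
  cx <- generate_complex(55, 8, 6)
  tr <- generate_trajectory(cx, generate_mobility(56, cx), n_frames = 25,
                            seed = 57)
  fl <- rmsf(tr, cx)
  cx$atoms$b_factor <- 10 + 5 * fl
  out <- bfactor_rmsf_validation(list(cx), list(tr))
  expect_equal(out$per_entry$correlation[1], 1, tolerance = 1e-9)
  expect_equal(out$mean_correlation, 1, tolerance = 1e-9)

  ## 85% identical B values trip the 80% modal rule
  cx2 <- cx
  nmod <- ceiling(0.85 * nrow(cx2$atoms))
  cx2$atoms$b_factor <- c(rep(20, nmod),
                          seq_len(nrow(cx2$atoms) - nmod) + 30)
  out2 <- bfactor_rmsf_validation(list(cx2), list(tr))
  expect_equal(out2$per_entry$status[1], "omitted_modal_b")
  expect_true(is.na(out2$per_entry$correlation[1]))
})
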