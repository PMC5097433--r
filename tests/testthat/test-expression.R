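test_that("rpkm follows the reads-per-kilobase-per-million formula", {
  # single gene: count 10, length 500 nt, column totals forced to 1e6 by a
  # filler gene
  counts <- toy_counts(
    c("g1", "filler"),
    rbind(c(10, 0, 0, 0, 0), c(1e6 - 10, 1e6, 1e6, 1e6, 1e6))
  )
  lens <- c(g1 = 500, filler = 1000)
  prof <- compute_rpkm(counts, lens)
  expect_equal(prof$rpkm_t0[1], 20.0)
})

test_that("an all-zero gene has zero rpkm and fails the read floor", {
  counts <- toy_counts(c("g1", "g2"),
                       rbind(c(0, 0, 0, 0, 0), c(100, 100, 100, 100, 100)))
  prof <- compute_rpkm(counts, c(g1 = 300, g2 = 300))
  expect_equal(unlist(prof[1, paste0("rpkm_", c("t0", "t1", "t2", "t3", "t4"))]),
               setNames(rep(0, 5), paste0("rpkm_", c("t0", "t1", "t2", "t3", "t4"))))
  expect_false(prof$passes_read_floor[1])
  expect_equal(prof$max_fold_vs_t0[1], 0)
})

test_that("a toy table matches a hand-computed rpkm matrix", {
  counts <- toy_counts(
    c("g1", "g2", "g3"),
    rbind(c(10, 20, 30, 40, 50),
          c(5, 5, 5, 5, 5),
          c(85, 75, 65, 55, 45))
  )
  lens <- c(g1 = 500, g2 = 1000, g3 = 2000)
  prof <- compute_rpkm(counts, lens)
  totals <- c(100, 100, 100, 100, 100)
  for (i in 1:3) {
    for (s in 1:5) {
      expected <- unname(1e9 * counts[[s + 1]][i] / (lens[i] * totals[s]))
      expect_equal(prof[[paste0("rpkm_", c("t0", "t1", "t2", "t3", "t4")[s])]][i],
                   expected)
    }
  }
  # peak stage is the argmax over t1..t4 with late tie-break
  expect_equal(prof$peak_stage, c("t4", "t4", "t1"))
})

test_that("degenerate tables raise named errors", {
  counts <- toy_counts(c("g1"), matrix(c(1, 0, 1, 1, 1), 1))
  expect_error(compute_rpkm(counts, c(g1 = 300)), "t1")
  counts2 <- toy_counts(c("g1", "g2"), matrix(1, 2, 5))
  expect_error(compute_rpkm(counts2, c(g1 = 300)), "g2")
})

test_that("rpkm is invariant under uniform scaling of a stage column", {
  counts <- toy_counts(c("g1", "g2"),
                       rbind(c(10, 30, 15, 12, 9), c(90, 70, 85, 88, 91)))
  lens <- c(g1 = 600, g2 = 900)
  scaled <- counts
  scaled$t2 <- scaled$t2 * 7L
  expect_equal(compute_rpkm(counts, lens)$rpkm_t2,
               compute_rpkm(scaled, lens)$rpkm_t2)
})

test_that("the threshold caller applies both the fold and read floors", {
  prof <- tibble::tibble(
    gene_id = c("up", "weak_fold", "low_reads"),
    max_count = c(50, 500, 19),
    max_fold_vs_t0 = c(3.5, 2.5, 100)
  )
  expect_equal(call_upregulated_a(prof), "up")
})

test_that("raising thresholds never enlarges the called set", {
  cfg <- fast_cfg(seed = 53, n_families_conserved = 40, frac_core_dev = 0.3)
  sim <- simulate_families(cfg)
  counts <- simulate_counts(sim$catalogue, sim$truth, cfg)
  prof <- compute_rpkm(counts$DD, sim$catalogue)
  base <- call_upregulated_a(prof, min_reads = 20, min_fold = 3)
  for (mf in c(4, 6, 10)) {
    expect_true(all(call_upregulated_a(prof, min_fold = mf) %in% base))
  }
  for (mr in c(50, 200)) {
    expect_true(all(call_upregulated_a(prof, min_reads = mr) %in% base))
  }
})

make_profile <- function(gene_id, rpkm) {
  out <- tibble::as_tibble(as.list(setNames(
    rpkm, paste0("rpkm_", c("t0", "t1", "t2", "t3", "t4")))))
  dplyr::bind_cols(tibble::tibble(gene_id = gene_id), out)
}

test_that("one-per-species families form a single matched group", {
  fams <- tibble::tibble(family_id = "f1",
                         gene_id = c("DD_1", "DL_1", "PP_1"),
                         species = c("DD", "DL", "PP"))
  profs <- dplyr::bind_rows(
    make_profile("DD_1", c(1, 10, 1, 1, 1)),
    make_profile("DL_1", c(1, 1, 1, 10, 1)), # anticorrelated on purpose
    make_profile("PP_1", c(1, 1, 1, 1, 10))
  )
  grp <- match_family_patterns(fams, profs)
  expect_equal(length(unique(grp$group_id)), 1)
  expect_equal(sort(grp$gene_id), c("DD_1", "DL_1", "PP_1"))
})

test_that("paralogs are matched to the ortholog with the same pattern", {
  fams <- tibble::tibble(family_id = "f1",
                         gene_id = c("DD_a", "DD_b", "PP_1"),
                         species = c("DD", "DD", "PP"))
  profs <- dplyr::bind_rows(
    make_profile("DD_a", c(1, 20, 2, 1, 1)),  # peaks t1
    make_profile("DD_b", c(1, 1, 2, 5, 20)),  # peaks t4
    make_profile("PP_1", c(2, 1, 3, 6, 25))   # peaks t4
  )
  grp <- match_family_patterns(fams, profs, min_similarity = 0.5)
  g_pp <- grp$group_id[grp$gene_id == "PP_1"]
  expect_equal(grp$group_id[grp$gene_id == "DD_b"], g_pp)
  expect_false(grp$group_id[grp$gene_id == "DD_a"] == g_pp)
})

test_that("ties in matching resolve by the documented gene-id order", {
  fams <- tibble::tibble(family_id = "f1",
                         gene_id = c("DD_a", "DD_b", "PP_a", "PP_b"),
                         species = c("DD", "DD", "PP", "PP"))
  p <- c(1, 2, 4, 8, 16)
  profs <- dplyr::bind_rows(
    make_profile("DD_a", p), make_profile("DD_b", p),
    make_profile("PP_a", p), make_profile("PP_b", p)
  )
  grp <- match_family_patterns(fams, profs)
  expect_equal(length(unique(grp$group_id)), 2)
  # lexicographically first pair matches first
  expect_equal(grp$group_id[grp$gene_id == "DD_a"],
               grp$group_id[grp$gene_id == "PP_a"])
  expect_equal(grp$group_id[grp$gene_id == "DD_b"],
               grp$group_id[grp$gene_id == "PP_b"])
})

test_that("zero-variance profiles get correlation zero, not NA", {
  fams <- tibble::tibble(family_id = "f1",
                         gene_id = c("DD_a", "DD_b", "PP_a"),
                         species = c("DD", "DD", "PP"))
  profs <- dplyr::bind_rows(
    make_profile("DD_a", rep(5, 5)),         # constant
    make_profile("DD_b", c(1, 2, 4, 8, 16)),
    make_profile("PP_a", c(1, 2, 4, 8, 16))
  )
  grp <- match_family_patterns(fams, profs, min_similarity = 0.5)
  expect_equal(grp$group_id[grp$gene_id == "DD_b"],
               grp$group_id[grp$gene_id == "PP_a"])
  # the constant profile stays unmatched
  expect_equal(sum(grp$group_id == grp$group_id[grp$gene_id == "DD_a"]), 1)
})

test_that("the three-of-four assembly rule admits and excludes correctly", {
  groups <- tibble::tibble(
    family_id = rep(c("f1", "f2", "f3"), times = c(4, 4, 3)),
    group_id = "g1",
    gene_id = c("DD_1", "DL_1", "PP_1", "DF_1",
                "DD_2", "DL_2", "PP_2", "DF_2",
                "DD_3", "DL_3", "PP_3"),
    species = c("DD", "DL", "PP", "DF",
                "DD", "DL", "PP", "DF",
                "DD", "DL", "PP")
  )
  called <- list(
    DD = c("DD_1", "DD_2", "DD_3"),
    DL = c("DL_1", "DL_3"),
    PP = c("PP_1", "PP_3"),
    DF = c("DF_1")
  )
  res <- assemble_method_a(called, groups, min_species = 3)
  # f1: called in 4 species -> in; f2: called in DD only -> out;
  # f3: spans 3 species, called in all 3 -> in
  expect_equal(res$dd_anchored_set, c("DD_1", "DD_3"))
})

test_that("method A recalls planted genes and degrades with asynchrony", {
  run <- function(asyn) {
    # planted fraction kept low so the compositional renormalisation of
    # rpkm (planted mass inflating the peak-stage library) stays small,
    # as it is in real transcriptomes
    cfg <- fast_cfg(seed = 59, n_families_conserved = 250,
                    n_species_specific_per_species = 0,
                    frac_core_dev = 0.08, asynchrony_mix = asyn,
                    fold_change_range = c(4, 20), dispersion = 0.01,
                    duplication_prob = 0, loss_prob = 0)
    sim <- simulate_families(cfg)
    counts <- simulate_counts(sim$catalogue, sim$truth, cfg)
    ma <- method_a(counts, sim$catalogue, truth_families(sim$catalogue))
    core_dd <- sim$catalogue$gene_id[sim$catalogue$species == "DD" &
                                       sim$catalogue$truth_core_dev]
    mean(core_dd %in% ma$dd_anchored_set)
  }
  recall0 <- run(0)
  expect_gte(recall0, 0.95)
  expect_lte(run(0.45), recall0)
})
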