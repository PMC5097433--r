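test_that("size factors match hand computations and an oracle", {
  # identical samples
  m <- cbind(a = c(10, 20, 30), b = c(10, 20, 30))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # doubling one sample
  m2 <- cbind(a = c(10, 20, 40), b = c(20, 40, 80))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # 5 x 3 toy matrix against explicit median enumeration
  set.seed(61)
  m3 <- matrix(rpois(15, 50) + 1, 5, 3)
  geo <- exp(rowMeans(log(m3)))
  ref <- apply(m3, 2, function(col) median(col / geo))
  expect_equal(unname(size_factors(m3)), unname(ref))
})

test_that("size factors agree with DESeq2 on a random matrix", {
  set.seed(67)
  m <- matrix(rnbinom(600, mu = 100, size = 5) + 1, 100, 6)
  # DESeq2 interpolates the median on the log scale for even unit counts;
  # agreement is to numerical interpolation differences only
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-3)
})

test_that("scaling one sample by c scales its relative size factor by c", {
  set.seed(71)
  m <- matrix(rpois(80, 60) + 1, 20, 4)
  s0 <- size_factors(m)
  m2 <- m
  m2[, 2] <- m2[, 2] * 5
  s1 <- size_factors(m2)
  expect_equal(s1[2] / s1[1], 5 * s0[2] / s0[1], tolerance = 1e-12)
})

test_that("size factors require a unit with all-positive counts", {
  m <- rbind(c(0, 5), c(5, 0))
  expect_error(size_factors(m), "positive")
})

test_that("dispersion estimates recover the simulation truth", {
  set.seed(73)
  cond <- rep(c("t0", "t3"), each = 4)
  # Poisson null: raw alpha concentrates near zero
  mp <- matrix(rpois(500 * 8, lambda = rep(exp(rnorm(500, 5, 0.5)), each = 8)),
               nrow = 500, byrow = TRUE)
  dp <- estimate_dispersion(mp, cond)
  expect_lt(median(dp$raw_alpha), 0.02)
  # NB truth alpha = 0.2
  mu <- exp(rnorm(500, 5, 0.5))
  mn <- matrix(rnbinom(500 * 8, mu = rep(mu, each = 8), size = 1 / 0.2),
               nrow = 500, byrow = TRUE)
  dn <- estimate_dispersion(mn, cond)
  expect_gt(median(dn$final_alpha), 0.1)
  expect_lt(median(dn$final_alpha), 0.4)
})

test_that("constant counts give zero raw dispersion and the trend value", {
  cond <- rep(c("t0", "t3"), each = 3)
  m <- rbind(rep(c(10, 20), each = 3),
             rep(c(100, 50), each = 3),
             rep(c(7, 7), each = 3))
  d <- estimate_dispersion(m, cond)
  expect_equal(d$raw_alpha, rep(0, 3))
  expect_equal(d$final_alpha, pmax(d$fitted_alpha, 1e-8))
})

test_that("dispersion estimation demands replicates", {
  expect_error(
    estimate_dispersion(matrix(1:4, 2, 2), c("t0", "t3")),
    "not estimable"
  )
})

test_that("the Wald test is null on identical conditions and exact on ratios", {
  y <- rep(c(40, 40), each = 4)
  sf <- rep(1, 8)
  x <- rep(c(0, 1), each = 4)
  r <- nb_stage_test(y, sf, x, alpha = 0.1)
  expect_lt(abs(r$log2_fold_change), 1e-8)
  expect_equal(r$p_value, 1)
  # exact doubling at tiny dispersion
  r2 <- nb_stage_test(rep(c(50, 100), each = 4), sf, x, alpha = 1e-10)
  expect_equal(r2$log2_fold_change, 1.0, tolerance = 1e-6)
  expect_lt(r2$p_value, 1e-10)
  # all-zero unit is flagged
  r3 <- nb_stage_test(rep(0, 8), sf, x, alpha = 0.1)
  expect_equal(r3$p_value, 1)
  expect_equal(r3$flag, "all_zero")
})

test_that("null p-values are approximately uniform", {
  set.seed(79)
  n <- 2000
  mu <- exp(rnorm(n, 5, 1))
  m <- matrix(rnbinom(n * 8, mu = rep(mu, each = 8), size = 1 / 0.1),
              nrow = n, byrow = TRUE)
  sf <- rep(1, 8)
  x <- rep(c(0L, 1L), each = 4)
  disp <- estimate_dispersion(m, rep(c("t0", "t3"), each = 4))
  p <- vapply(seq_len(n), function(i) {
    nb_stage_test(m[i, ], sf, x, disp$final_alpha[i])$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif")$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("Benjamini-Hochberg matches the hand step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(bh_adjust(p), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(83)
  pr <- runif(50)
  expect_equal(bh_adjust(pr), bh_ref(pr))
  expect_true(all(bh_adjust(pr) >= pr))
  # order preservation
  expect_equal(order(bh_adjust(pr)[order(pr)]), seq_len(50))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1|\\[0, 1\\]")
})

test_that("calling is up-direction filtered at the target FDR", {
  # two units: one truly up at t3, one truly down
  set.seed(89)
  samples <- tidyr::expand_grid(replicate = c("DD", "DL", "PP", "DF"),
                                stage = c("t0", "t1", "t2", "t3", "t4")) |>
    dplyr::mutate(sample = paste(replicate, stage, sep = ":"))
  mk_counts <- function(mu_by_stage) {
    vapply(seq_len(nrow(samples)), function(j) {
      rpois(1, mu_by_stage[[samples$stage[j]]])
    }, numeric(1))
  }
  up <- mk_counts(list(t0 = 50, t1 = 60, t2 = 80, t3 = 400, t4 = 300))
  down <- mk_counts(list(t0 = 400, t1 = 100, t2 = 60, t3 = 50, t4 = 50))
  flat <- mk_counts(list(t0 = 100, t1 = 100, t2 = 100, t3 = 100, t4 = 100))
  design <- structure(
    list(counts = rbind(up = up, down = down, flat = flat),
         samples = samples,
         unit_map = tibble::tibble(unit_id = c("up", "down", "flat"))),
    class = "replicate_design"
  )
  fit <- call_method(design, fdr = 0.10)
  expect_true("up" %in% fit$called)
  expect_false("down" %in% fit$called)
  res_down <- fit$results[fit$results$unit_id == "down", ]
  expect_true(all(res_down$log2_fold_change < 0))
  expect_true(all(fit$results$q_value >= fit$results$p_value))
})

test_that("species-replicate designs admit only one-per-species families", {
  cat <- toy_catalogue(n_fam = 4)
  fams <- truth_families(cat)
  # break family F002: drop its DL member; duplicate a DD member in F003
  fams <- fams[!(fams$family_id == "F002" & fams$species == "DL"), ]
  fams <- dplyr::bind_rows(
    fams,
    tibble::tibble(family_id = "F003", gene_id = "DD_extra", species = "DD")
  )
  counts <- lapply(
    stats::setNames(c("DD", "DL", "PP", "DF"), c("DD", "DL", "PP", "DF")),
    function(sp) {
      ids <- unique(c(cat$gene_id[cat$species == sp],
                      if (sp == "DD") "DD_extra"))
      toy_counts(ids, matrix(50L, length(ids), 5))
    }
  )
  d <- design_species_replicates(counts, fams)
  expect_equal(sort(rownames(d$counts)), c("F001", "F004"))
  expect_equal(ncol(d$counts), 20)
})

test_that("method B sees shared regulation but not DD-only regulation", {
  cat <- toy_catalogue(n_fam = 100, planted = 1:8, fold = 10, peak = "t3")
  cfg <- sim_config(seed = 97, dispersion = 0.05, asynchrony_mix = 0)
  truth_all <- truth_of(cat)
  counts_all <- simulate_counts(cat, truth_all, cfg)
  # same catalogue, but the planted signal restricted to DD
  cat_dd <- cat
  dd_only <- cat_dd$species != "DD"
  cat_dd$truth_peak_stage[dd_only] <- NA
  cat_dd$truth_fold[dd_only] <- NA
  cat_dd$truth_core_dev[dd_only] <- FALSE
  counts_dd <- simulate_counts(cat_dd, truth_of(cat_dd), cfg)

  fams <- truth_families(cat)
  planted_fams <- sprintf("F%03d", 1:8)
  rec_all <- mean(planted_fams %in% method_b(counts_all, fams)$called)
  rec_dd <- mean(planted_fams %in% method_b(counts_dd, fams)$called)
  expect_gte(rec_all, 0.8)
  expect_lt(rec_dd, rec_all)
  # the DD threshold caller still sees the DD-only signal
  prof_dd <- compute_rpkm(counts_dd$DD, cat)
  called_dd <- call_upregulated_a(prof_dd)
  planted_dd <- cat$gene_id[cat$species == "DD" & cat$truth_core_dev]
  expect_gte(mean(planted_dd %in% called_dd), 0.9)
})
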