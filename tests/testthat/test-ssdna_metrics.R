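cluster_row <- function(sample_id = "s1", chrom = "chr1", start = 1000,
                        length = 10000, n = 10,
                        type = "C_coordinated", selected = FALSE) {
  data.frame(sample_id = sample_id, cluster_id = paste0(sample_id, "_c"),
             chrom = chrom, start = start, end = start + length,
             length = length, n_mutations = n, k = n, x = length + 1,
             p_value = 1e-9, selected = selected, type = type,
             class = unname(hypermut:::type_to_class(type)),
             stringsAsFactors = FALSE)
}

test_that("percent ssDNA implements sum-of-cluster-lengths over genome size", {
  dip <- genome_model("chr1", 12070000, ploidy = 2)   # ~24.14 Mb total
  cl <- rbind(cluster_row(length = 110000), cluster_row(length = 100000))
  out <- ssdna_fraction(cl, dip)
  expect_equal(out$sum_cluster_length, 210000)
  expect_equal(out$percent_ssDNA, 100 * 210000 / 24140000)
  expect_equal(round(out$percent_ssDNA, 1), 0.9)     # diploid-scale estimate
  hap <- genome_model("chr1", 12070000, ploidy = 1)
  out_h <- ssdna_fraction(cluster_row(length = 28000), hap)
  expect_equal(round(out_h$percent_ssDNA, 1), 0.2)
  # non-CG and undersized clusters never count
  cl2 <- rbind(cluster_row(length = 50000),
               cluster_row(length = 999999, type = "non_CG"),
               cluster_row(length = 999999, type = "below_size_filter"))
  expect_equal(ssdna_fraction(cl2, hap)$sum_cluster_length, 50000)
  # zero clusters -> 0%
  empty <- cl[0, ]
  empty[1, "sample_id"] <- "s9"; empty <- empty[0, ]
  expect_equal(nrow(ssdna_fraction(empty, hap)), 0)
})

test_that("percent ssDNA is additive and halves when ploidy doubles", {
  hap <- genome_model("chr1", 1e7, ploidy = 1)
  dip <- genome_model("chr1", 1e7, ploidy = 2)
  cl <- rbind(cluster_row(length = 5000), cluster_row(length = 15000))
  a <- ssdna_fraction(cl[1, ], hap)$percent_ssDNA
  b <- ssdna_fraction(cl[2, ], hap)$percent_ssDNA
  both <- ssdna_fraction(cl, hap)$percent_ssDNA
  expect_equal(both, a + b)
  expect_equal(ssdna_fraction(cl, dip)$percent_ssDNA, both / 2)
  # order invariance
  expect_equal(ssdna_fraction(cl[2:1, ], hap)$percent_ssDNA, both)
})

test_that("cluster density is mutations per kb", {
  expect_equal(cluster_density(10, 10000), 1)
  expect_equal(cluster_density(5, 1000), 5)
  expect_error(cluster_density(3, 0), "positive")
})

test_that("chromosome distribution regresses counts on length", {
  g <- genome_model(paste0("c", 1:8), (1:8) * 1e5)
  # counts exactly proportional to length
  cl <- do.call(rbind, lapply(1:8, function(i) {
    n <- i  # 1 cluster per 1e5 bp
    do.call(rbind, lapply(seq_len(n), function(j)
      cluster_row(chrom = paste0("c", i), start = j * 1000)))
  }))
  res <- chromosome_distribution(cl, g)
  expect_false(res$degenerate)
  expect_lt(res$p, 1e-6)
  expect_equal(res$intercept, 0, tolerance = 1e-8)
  expect_equal(res$slope, 1e-5, tolerance = 1e-8)
  # all clusters on one chromosome: flagged degenerate, proportionality off
  cl1 <- do.call(rbind, lapply(1:8, function(j)
    cluster_row(chrom = "c3", start = j * 50000)))
  res1 <- chromosome_distribution(cl1, g)
  expect_true(res1$degenerate)
})

test_that("uniform simulation spreads clusters proportionally to size", {
  set.seed(61)
  g <- random_genome(c(cA = 3e5, cB = 2e5, cC = 1e5), gc = 0.38)
  cfg <- sim_config(n_dsb = 60, background_rate = 0,
                    mechanism_mix = c(unidirectional_resection = 1),
                    tract_meanlog = log(2000), tract_sdlog = 0.3)
  sim <- simulate_catalog(g, cfg, seed = 62)
  calls <- detect_clusters(sim$mutations[, 1:5], g)
  res <- chromosome_distribution(calls$clusters, g)
  expect_false(res$degenerate)
  expect_gt(res$slope, 0)
  expect_lt(res$p, 0.5)  # 3 points: only direction is meaningful
  # heaviest chromosome gets the most clusters
  tab <- res$table
  expect_equal(which.max(tab$n_clusters), which.max(tab$length))
})

test_that("cohort summaries compute incidence and paired comparisons", {
  meta <- data.frame(sample_id = paste0("s", 1:10),
                     group = rep(c("gamma", "no_gamma"), each = 5))
  # 8 of 10 with >=1 nonselected cluster; all gamma, 3 of 5 no_gamma
  cl <- do.call(rbind, c(
    lapply(paste0("s", 1:5), function(s) cluster_row(sample_id = s)),
    lapply(paste0("s", 6:8), function(s) cluster_row(sample_id = s))))
  cl$cluster_id <- paste0(cl$sample_id, "_c1")
  calls <- structure(list(clusters = cl,
                          mutations = make_catalog(1:2),
                          pi = c(), params = list()),
                     class = "cluster_calls")
  out <- cohort_summaries(calls, meta, group_col = "group")
  expect_equal(sum(out$incidence$n_with_cluster), 8)
  expect_equal(out$incidence$percent_with_cluster,
               c(100, 60))
  expect_equal(nrow(out$incidence_tests), 1)
  # identical strata compare with p = 1
  meta2 <- data.frame(sample_id = paste0("s", 1:4),
                      group = rep(c("a", "b"), each = 2))
  cl2 <- do.call(rbind, lapply(paste0("s", c(1, 3)), function(s)
    cluster_row(sample_id = s)))
  calls2 <- structure(list(clusters = cl2, mutations = make_catalog(1:2),
                           pi = c(), params = list()),
                      class = "cluster_calls")
  out2 <- cohort_summaries(calls2, meta2, group_col = "group")
  expect_equal(out2$incidence_tests$p, 1)
  # selected clusters are excluded from nonselected incidence
  cl3 <- cluster_row(sample_id = "s1", selected = TRUE)
  calls3 <- structure(list(clusters = cl3, mutations = make_catalog(1:2),
                           pi = c(), params = list()),
                      class = "cluster_calls")
  out3 <- cohort_summaries(calls3, meta2, group_col = "group")
  expect_equal(sum(out3$incidence$n_with_cluster), 0)
})

test_that("gamma-like and null cohorts separate on cluster incidence", {
  set.seed(71)
  g <- random_genome(c(chr1 = 4e5), gc = 0.38)
  meta <- data.frame(sample_id = paste0("i", 1:10),
                     group = rep(c("gamma", "none"), each = 5))
  muts <- list()
  for (i in 1:5)
    muts[[i]] <- simulate_catalog(
      g, sim_config(n_dsb = 2, background_rate = 5e-5),
      sample_id = paste0("i", i), seed = 700 + i)$mutations[, 1:5]
  for (i in 6:10)
    muts[[i]] <- simulate_null(g, 20, sample_id = paste0("i", i),
                               seed = 700 + i)
  calls <- detect_clusters(do.call(rbind, muts), g)
  out <- cohort_summaries(calls, meta, group_col = "group")
  inc <- out$incidence
  expect_gt(inc$percent_with_cluster[inc$group == "gamma"],
            inc$percent_with_cluster[inc$group == "none"])
  expect_lt(out$incidence_tests$p, 0.05)
})
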