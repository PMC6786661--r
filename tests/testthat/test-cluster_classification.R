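split1 <- function(s) strsplit(s, "")[[1]]

test_that("pattern classification covers the taxonomy", {
  cases <- list(
    CCCC = "C_coordinated",
    GGGG = "G_coordinated",
    CCGG = "CG_single_switch_5pC",
    GGCC = "CG_single_switch_5pG",
    CCCG = "C_coordinated_terminal_G",
    GCCC = "C_coordinated_terminal_G",   # lone G at the 5' side
    CGGG = "G_coordinated_terminal_C",
    GGGC = "G_coordinated_terminal_C",
    CGCG = "CG_multiple_switch",
    CCGC = "CG_multiple_switch",         # lone G internal breaks the C run
    CCGGG = "CG_single_switch_5pC",
    CCC = "below_size_filter",           # 3 mutations: under the >3 filter
    CCAC = "non_CG",
    TTTT = "non_CG")
  for (pat in names(cases))
    expect_equal(classify_pattern(split1(pat)), cases[[pat]], label = pat)
  expect_error(classify_pattern(character(0)), "empty")
  # non-CG takes precedence over the size filter
  expect_equal(classify_pattern(split1("CA")), "non_CG")
})

test_that("classifier agrees with an independent switch-count oracle", {
  set.seed(202)
  for (i in 1:2000) {
    pat <- sample(c("C", "G"), sample(4:50, 1), replace = TRUE)
    expect_equal(classify_pattern(pat), oracle_classify(pat),
                 label = paste(pat, collapse = ""))
  }
})

test_that("reverse-complementing a pattern swaps C and G roles", {
  swap <- c(C_coordinated = "G_coordinated",
            G_coordinated = "C_coordinated",
            C_coordinated_terminal_G = "G_coordinated_terminal_C",
            G_coordinated_terminal_C = "C_coordinated_terminal_G",
            CG_single_switch_5pC = "CG_single_switch_5pC",
            CG_single_switch_5pG = "CG_single_switch_5pG",
            CG_multiple_switch = "CG_multiple_switch")
  set.seed(303)
  for (i in 1:500) {
    pat <- sample(c("C", "G"), sample(4:30, 1), replace = TRUE)
    rc <- rev(ifelse(pat == "C", "G", "C"))
    expect_equal(classify_pattern(rc),
                 unname(swap[classify_pattern(pat)]))
  }
})

make_classified <- function(pos_list, ref_list) {
  # build a cluster_calls object from per-cluster positions/refs; clusters
  # sit far apart on one long chromosome so detection keeps them separate
  stopifnot(length(pos_list) == length(ref_list))
  g <- genome_model("chr1", 12070000)
  muts <- do.call(rbind, lapply(seq_along(pos_list), function(i)
    make_catalog(pos_list[[i]], ref = ref_list[[i]], chrom = "chr1",
                 sample_id = "s1")))
  calls <- detect_clusters(muts, g)
  classify_clusters(calls)
}

test_that("cluster-level classification and switch geometry use positions", {
  calls <- make_classified(
    pos_list = list(100000 + c(0, 100, 300, 600),        # CCGG
                    3000000 + c(0, 50, 100, 150, 200),   # CCCCC
                    5000000 + c(0, 200, 400, 5000)),     # CCCG terminal
    ref_list = list(c("C", "C", "G", "G"),
                    rep("C", 5),
                    c("C", "C", "C", "G")))
  cl <- calls$clusters[order(calls$clusters$start), ]
  expect_equal(cl$type, c("CG_single_switch_5pC", "C_coordinated",
                          "C_coordinated_terminal_G"))
  ss <- cl[cl$type == "CG_single_switch_5pC", ]
  expect_equal(ss$left_arm_bp, 100)    # outermost-to-innermost of the C run
  expect_equal(ss$right_arm_bp, 300)
  tg <- cl[cl$type == "C_coordinated_terminal_G", ]
  expect_equal(tg$nonmatched_dist, 4600)
  expect_equal(tg$matched_dist, 200)
})

test_that("type distribution reports fractions over the displayed classes", {
  types <- c(rep("C_coordinated", 10), rep("G_coordinated", 8),
             rep("CG_single_switch_5pC", 1), rep("CG_multiple_switch", 5),
             rep("non_CG", 7), rep("below_size_filter", 3))
  cl <- data.frame(type = types,
                   class = unname(hypermut:::type_to_class(types)))
  td <- type_distribution(cl)
  expect_equal(sum(td$fraction), 1)
  expect_equal(td$n[td$class == "coordinated"], 18)
  # 1-of-24 single switch, as in a resection-deficient strain
  expect_equal(td$fraction[td$class == "single_switch"], 1 / 24)
  # two identical strata give identical rows
  td2 <- type_distribution(rbind(cl, cl), rep(c("a", "b"), each = nrow(cl)))
  expect_equal(td2$fraction[td2$stratum == "a"],
               td2$fraction[td2$stratum == "b"])
  # empty stratum: zero counts, no error
  td3 <- type_distribution(cl[0, ])
  expect_true(all(td3$n == 0))
})

test_that("switch-direction summary counts 5'C vs 5'G polarity", {
  cl <- data.frame(type = c("CG_single_switch_5pC", "CG_single_switch_5pC",
                            "CG_single_switch_5pG", "C_coordinated"))
  s <- switch_direction_summary(cl)
  expect_equal(s$n, 3)
  expect_equal(s$frac_5pC_3pG, 2 / 3)
  expect_equal(s$frac_5pG_3pC, 1 / 3)
  expect_warning(s0 <- switch_direction_summary(
    data.frame(type = "C_coordinated")), "undefined")
  expect_true(is.na(s0$frac_5pC_3pG))
})

test_that("terminal distances separate appended mutations from tract ends", {
  # C at 100,200,300 with a lone G at 5000: nonmatched 4700, matched 100
  calls <- make_classified(list(c(100, 200, 300, 5000)),
                           list(c("C", "C", "C", "G")))
  res <- terminal_distance_analysis(calls$clusters)
  expect_equal(res$nonmatched, 4700)
  expect_equal(res$matched, 100)
  # symmetric case: G at 10; C at 20,30,40
  calls2 <- make_classified(list(c(10, 20, 30, 40)),
                            list(c("G", "C", "C", "C")))
  res2 <- terminal_distance_analysis(calls2$clusters)
  expect_equal(res2$nonmatched, 10)
  expect_equal(res2$matched, 10)
})

test_that("rank-sum direction distinguishes true switches from co-location", {
  # generative check: coordinated tracts with a far, unrelated terminal base
  # show larger nonmatched than matched distances
  set.seed(404)
  pos_list <- list(); ref_list <- list()
  for (i in 1:30) {
    tract <- sort(sample(1:2000, 5))
    far <- 2000 + sample(3000:8000, 1)
    pos_list[[i]] <- 1e5 + (i - 1) * 3e5 + c(tract, far)
    ref_list[[i]] <- c(rep("C", 5), "G")
  }
  g <- genome_model("chr1", 12070000)
  muts <- do.call(rbind, lapply(seq_along(pos_list), function(i)
    make_catalog(pos_list[[i]], ref = ref_list[[i]], chrom = "chr1")))
  calls <- classify_clusters(detect_clusters(muts, g))
  tt <- calls$clusters[calls$clusters$type == "C_coordinated_terminal_G", ]
  expect_gt(nrow(tt), 20)
  res <- terminal_distance_analysis(calls$clusters)
  expect_gt(median(res$nonmatched), median(res$matched))
  expect_lt(res$test$p.value, 0.01)
})

test_that("arm-ratio variance flags asymmetric strata", {
  cl <- data.frame(type = rep("CG_single_switch_5pC", 6),
                   left_arm_bp = c(1000, 1000, 1000, 100, 1000, 10000),
                   right_arm_bp = c(1000, 1000, 1000, 1000, 1000, 1000))
  out <- arm_ratio_variance(cl, strata = rep(c("sym", "asym"), each = 3))
  expect_equal(unname(out$variance["sym"]), 0)
  expect_gt(out$variance["asym"], out$variance["sym"])
  expect_equal(nrow(out$tests), 1)
})
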