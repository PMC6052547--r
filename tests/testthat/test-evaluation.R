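test_that("positional cosine matches hand computations", {
  p <- random_profile(6, seed = 1)
  expect_equal(positional_cosine(p, p), rep(1, 6))

  onehot_a <- matrix(c(1, rep(0, 19)), 1, 20)
  onehot_c <- matrix(c(0, 1, rep(0, 18)), 1, 20)
  expect_equal(positional_cosine(onehot_a, onehot_c), 0)

  uniform <- matrix(1 / 20, 1, 20)
  expect_equal(positional_cosine(uniform, onehot_a),
               0.05 / sqrt(20 * 0.05^2))
  expect_equal(round(positional_cosine(uniform, onehot_a), 4), 0.2236)

  expect_error(positional_cosine(matrix(0, 1, 20), onehot_a), "zero-norm")
})

test_that("cosine is invariant to positive rescaling of rows", {
  a <- unclass(random_profile(4, seed = 2))
  b <- unclass(random_profile(4, seed = 3))
  expect_equal(positional_cosine(3.7 * a, b), positional_cosine(a, b))
  expect_equal(positional_cosine(a, 0.2 * b), positional_cosine(a, b))
})

test_that("ragged by-position aggregation ignores absent positions", {
  a1 <- unclass(random_profile(3, seed = 4)); t1 <- unclass(random_profile(3))
  a2 <- unclass(random_profile(5, seed = 5)); t2 <- unclass(random_profile(5))
  curve <- positional_cosine_curve(list(a1, a2), list(t1, t2))
  expect_equal(curve$n, c(2L, 2L, 2L, 1L, 1L))
  c1 <- positional_cosine(a1, t1); c2 <- positional_cosine(a2, t2)
  expect_equal(curve$mean_cosine[1], (c1[1] + c2[1]) / 2)
  expect_equal(curve$mean_cosine[4], c2[4])
})

test_that("hit labeling follows the superfamily/fold/class rule", {
  annot <- toy_annotation()
  hits <- tibble::tibble(
    query =   c("d1", "d1", "d1", "d1", "d1"),
    subject = c("d2", "d3", "d4", "d5", "d1"),
    evalue = c(1e-10, 1e-8, 1e-6, 1e-4, 1e-2)
  )
  lab <- label_hits(hits, annot)
  # same superfamily; same fold diff superfamily; diff class; diff fold; self
  expect_equal(as.character(lab$label),
               c("TP", "unknown", "FP", "FP", "unknown"))
  expect_equal(lab$query_superfamily, rep("a.1.1", 5))

  expect_error(label_hits(tibble::tibble(query = "d1", subject = "zz",
                                         evalue = 1), annot),
               "zz")
})

test_that("weighted ROC accumulates 1/superfamily-size per counted hit", {
  annot <- toy_annotation()  # a.1.1 has 3 members
  hits <- tibble::tibble(
    query = c("d1", "d2", "d1"),
    subject = c("d2", "d6", "d4"),
    evalue = c(1e-9, 1e-8, 1e-7)
  )
  curve <- weighted_roc(label_hits(hits, annot), annot)
  expect_s3_class(curve, "seqprof_roc")
  expect_equal(curve$fp, c(0, 0, 0, 1 / 3))
  expect_equal(curve$tp, c(0, 1 / 3, 2 / 3, 2 / 3))
  expect_true(all(diff(curve$fp) >= 0))
  expect_true(all(diff(curve$tp) >= 0))

  # two queries from a 2-member superfamily, one FP each: total weighted FP 1
  annot2 <- tibble::tibble(domain = c("q1", "q2", "x1"),
                           class = c("a", "a", "b"),
                           fold = c("a.1", "a.1", "b.1"),
                           superfamily = c("a.1.1", "a.1.1", "b.1.1"),
                           family = c("a.1.1.1", "a.1.1.1", "b.1.1.1"))
  hits2 <- tibble::tibble(query = c("q1", "q2"), subject = c("x1", "x1"),
                          evalue = c(1e-5, 1e-4))
  curve2 <- weighted_roc(label_hits(hits2, annot2), annot2)
  expect_equal(max(curve2$fp), 1)
})

test_that("one FP per query accumulates one unit per distinct superfamily", {
  set.seed(6)
  n_sf <- 5
  annot <- tibble::tibble(
    domain = sprintf("m%02d", 1:20),
    class = "a",
    fold = paste0("a.", rep(1:n_sf, each = 4)),
    superfamily = paste0("a.", rep(1:n_sf, each = 4), ".1"),
    family = paste0("a.", rep(1:n_sf, each = 4), ".1.1")
  )
  decoy <- tibble::tibble(domain = "decoy", class = "b", fold = "b.1",
                          superfamily = "b.1.1", family = "b.1.1.1")
  annot <- rbind(annot, decoy)
  queries <- annot$domain[annot$class == "a"]
  hits <- tibble::tibble(query = queries, subject = "decoy",
                         evalue = stats::runif(length(queries)))
  curve <- weighted_roc(label_hits(hits, annot), annot)
  expect_equal(max(curve$fp), n_sf)
})

test_that("pAUC handles the perfect, empty and budget-limited cases", {
  annot <- toy_annotation()
  hits <- tibble::tibble(query = c("d1", "d1", "d1"),
                         subject = c("d2", "d6", "d4"),
                         evalue = c(1e-9, 1e-8, 1e-7))
  curve <- weighted_roc(label_hits(hits, annot), annot)
  # all TPs precede the FP: area is full up to any budget
  expect_equal(pauc(curve, fp_limit = 1 / 3, tp_max = 2 / 3), 1)

  no_tp <- tibble::tibble(query = "d1", subject = "d4", evalue = 1e-3)
  c2 <- weighted_roc(label_hits(no_tp, annot), annot)
  expect_equal(pauc(c2, fp_limit = 1, tp_max = 1), 0)

  expect_error(pauc(c2[0, ], 1, 1), "empty")
  expect_error(pauc(c2, -1, 1), "positive")
})

test_that("pAUC equals the brute-force oracle on random hit lists", {
  set.seed(77)
  for (i in 1:100) {
    rl <- random_labeled_hits(n_hits = 30)
    lab <- label_hits(rl$hits, rl$annotation)
    if (!any(lab$label %in% c("TP", "FP"))) next
    curve <- weighted_roc(lab, rl$annotation)
    tp_max <- max(max(curve$tp), 0.5)
    fp_limit <- stats::runif(1, 0.2, max(max(curve$fp), 0.4) + 0.5)
    expect_equal(pauc(curve, fp_limit, tp_max),
                 pauc_oracle(lab, rl$annotation, fp_limit, tp_max),
                 tolerance = 1e-12)
  }
})

test_that("relabeling any FP as TP never decreases the pAUC", {
  set.seed(13)
  for (i in 1:20) {
    rl <- random_labeled_hits(n_hits = 25)
    lab <- label_hits(rl$hits, rl$annotation)
    fps <- which(lab$label == "FP")
    if (length(fps) == 0) next
    curve <- weighted_roc(lab, rl$annotation)
    tp_max <- max(curve$tp) + 2
    p0 <- pauc(curve, 1.5, tp_max)
    lab2 <- lab
    lab2$label[sample(fps, 1)] <- "TP"
    p1 <- pauc(weighted_roc(lab2, rl$annotation), 1.5, tp_max)
    expect_gte(p1 + 1e-12, p0)
  }
})

test_that("permuting tied hits moves the pAUC by at most one hit weight", {
  set.seed(29)
  for (i in 1:20) {
    rl <- random_labeled_hits(n_hits = 20)
    rl$hits$evalue <- sample(c(1e-5, 1e-4), 20, replace = TRUE)  # heavy ties
    lab <- label_hits(rl$hits, rl$annotation)
    curve <- weighted_roc(lab, rl$annotation)
    tp_max <- max(max(curve$tp), 1)
    fp_limit <- 1
    p0 <- pauc(curve, fp_limit, tp_max)
    perm <- sample(nrow(rl$hits))
    lab_p <- lab[perm, ]
    p1 <- pauc(weighted_roc(lab_p, rl$annotation), fp_limit, tp_max)
    counts <- table(rl$annotation$superfamily)
    wmax <- 1 / min(as.numeric(counts[as.character(lab$query_superfamily)]))
    expect_lte(abs(p1 - p0), wmax / fp_limit + 1e-12)
  }
})

test_that("relative sensitivity is a plain pAUC ratio", {
  expect_equal(relative_sensitivity(0.3, 0.3), 1)
  expect_equal(relative_sensitivity(0.217, 0.140), 0.217 / 0.140)
  expect_equal(round(relative_sensitivity(0.217, 0.140), 2), 1.55)
  a <- 0.4; b <- 0.25
  expect_equal(relative_sensitivity(a, b) * relative_sensitivity(b, a), 1)
  expect_error(relative_sensitivity(0.2, 0), "positive")
})
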