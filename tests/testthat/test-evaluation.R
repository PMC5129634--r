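gold1 <- gold_standard("g1", "1.1.1.1")

test_that("classify applies the TP/FP/FN rules including the missing-gene rule", {
  # exact match
  cf <- classify(prediction_set("r", list(g1 = "1.1.1.1"), "g1"), gold1)
  expect_equal(c(cf$tp, cf$fp, cf$fn), c(1L, 0L, 0L))
  # mismatching label is both a false positive and a false negative
  cf2 <- classify(prediction_set("r", list(g1 = "2.2.2.2"), "g1"), gold1)
  expect_equal(c(cf2$tp, cf2$fp, cf2$fn), c(0L, 1L, 1L))
  # gold gene absent from the universe: all its labels are false negatives
  gold2 <- gold_standard(c("g1", "g1"), c("1.1.1.1", "2.2.2.2"))
  cf3 <- classify(prediction_set("r", list(gX = "1.1.1.1"), "gX"), gold2)
  expect_equal(c(cf3$tp, cf3$fp, cf3$fn), c(0L, 0L, 2L))
  expect_false(cf3$per_gene$in_universe)
  # predictions on non-gold genes contribute nothing
  cf4 <- classify(prediction_set("r", list(g1 = "1.1.1.1", g9 = "5.5.5.5"),
                                 c("g1", "g9")), gold1)
  expect_equal(c(cf4$tp, cf4$fp, cf4$fn), c(1L, 0L, 0L))
  # partial EC labels match only identical partial labels
  goldp <- gold_standard("g1", "2.7.7.-")
  cfp <- classify(prediction_set("r", list(g1 = "2.7.7.7"), "g1"), goldp)
  expect_equal(c(cfp$tp, cfp$fp, cfp$fn), c(0L, 1L, 1L))
})

test_that("metrics implements precision, recall and F-measure", {
  m <- metrics(confusion_counts(1326, 213, 149))
  expect_equal(m$precision, 1326 / (1326 + 213))
  expect_equal(m$recall, 1326 / (1326 + 149))
  expect_equal(m$f_measure,
               2 * m$precision * m$recall / (m$precision + m$recall))
  expect_equal(round(c(m$precision, m$recall, m$f_measure), 2),
               c(0.86, 0.90, 0.88))
  m2 <- metrics(confusion_counts(1235, 436, 240))
  expect_equal(round(c(m2$precision, m2$recall, m2$f_measure), 2),
               c(0.74, 0.84, 0.79))
  # perfect prediction and degenerate zero denominators
  expect_equal(unlist(metrics(confusion_counts(10, 0, 0))[1:3]),
               c(precision = 1, recall = 1, f_measure = 1))
  expect_equal(unlist(metrics(confusion_counts(0, 0, 0))[1:3]),
               c(precision = 0, recall = 0, f_measure = 0))
  # F lies between precision and recall when defined
  m3 <- metrics(confusion_counts(50, 30, 5))
  expect_gte(m3$f_measure, min(m3$precision, m3$recall))
  expect_lte(m3$f_measure, max(m3$precision, m3$recall))
})

test_that("merge_predictions unions labels and universes and is idempotent", {
  a <- prediction_set("a", list(g1 = "1.1.1.1"), c("g1", "g2"))
  b <- prediction_set("b", list(g1 = "2.2.2.2"), "g1")
  m <- merge_predictions(a, b)
  expect_equal(m$predictions$ec_label, c("1.1.1.1", "2.2.2.2"))
  expect_equal(m$gene_universe, c("g1", "g2"))
  expect_equal(m$name, "a+b")
  aa <- merge_predictions(a, a)
  expect_identical(aa$predictions, a$predictions)
  expect_identical(aa$gene_universe, a$gene_universe)
})

test_that("classify agrees with a brute-force oracle and merging is monotone", {
  set.seed(31)
  n_rounds <- 5L
  for (round in seq_len(n_rounds)) {
    genes <- sprintf("g%02d", 1:50)
    rand_sets <- function(p_has, max_k) {
      sets <- lapply(genes, function(g) {
        if (runif(1) > p_has) return(character(0))
        sprintf("%d.%d.%d.%d", sample(1:6, max_k, TRUE),
                sample(1:3, max_k, TRUE), sample(1:3, max_k, TRUE),
                sample(1:5, max_k, TRUE))
      })
      stats::setNames(lapply(sets, unique), genes)
    }
    gold_sets <- rand_sets(0.8, 2)
    gold_sets <- gold_sets[lengths(gold_sets) > 0]
    gold <- gold_standard(rep(names(gold_sets), lengths(gold_sets)),
                          unlist(gold_sets, use.names = FALSE))
    uni_a <- sample(genes, 40)
    uni_b <- sample(genes, 45)
    pred_sets_a <- rand_sets(0.7, 2)[uni_a]
    pred_sets_b <- rand_sets(0.7, 2)[uni_b]
    mk <- function(nm, sets, uni) {
      sets <- sets[lengths(sets) > 0]
      prediction_set(nm, sets, uni)
    }
    a <- mk("a", pred_sets_a, uni_a)
    b <- mk("b", pred_sets_b, uni_b)
    # brute-force per-gene set-difference oracle
    brute <- function(pred) {
      tp <- fp <- fn <- 0L
      for (g in names(gold_sets)) {
        gl <- gold_sets[[g]]
        pl <- if (g %in% pred$gene_universe) {
          pred$predictions$ec_label[pred$predictions$gene_id == g]
        } else character(0)
        tp <- tp + length(intersect(pl, gl))
        fp <- fp + length(setdiff(pl, gl))
        fn <- fn + length(setdiff(gl, pl))
      }
      c(tp = tp, fp = fp, fn = fn)
    }
    for (p in list(a, b)) {
      cf <- classify(p, gold)
      expect_identical(c(tp = cf$tp, fp = cf$fp, fn = cf$fn), brute(p))
      # conservation and per-gene consistency
      expect_true(check_conservation(cf))
      expect_equal(cf$tp, sum(cf$per_gene$tp))
      expect_equal(cf$fp, sum(cf$per_gene$fp))
      expect_equal(cf$fn, sum(cf$per_gene$fn))
    }
    cfa <- classify(a, gold); cfb <- classify(b, gold)
    cfm <- classify(merge_predictions(a, b), gold)
    expect_gte(cfm$tp, max(cfa$tp, cfb$tp))
    expect_lte(cfm$fn, min(cfa$fn, cfb$fn))
    expect_lte(cfm$fp, cfa$fp + cfb$fp)
    expect_identical(c(tp = cfm$tp, fp = cfm$fp, fn = cfm$fn),
                     brute(merge_predictions(a, b)))
  }
})

test_that("prediction sets enforce the universe invariant and round-trip TSV", {
  expect_error(prediction_set("r", list(g1 = "1.1.1.1"), "g2"),
               "not in the gene universe")
  d <- withr::local_tempdir()
  p <- prediction_set("res1", list(g1 = c("1.1.1.1", "2.2.2.2")),
                      c("g1", "g2"))
  write_prediction_set(p, d)
  p2 <- read_prediction_set("res1", file.path(d, "res1.predictions.tsv"),
                            file.path(d, "res1.universe.txt"))
  expect_identical(p2$predictions, p$predictions)
  expect_identical(p2$gene_universe, p$gene_universe)
})

test_that("check_conservation flags inconsistent external counts", {
  expect_true(check_conservation(confusion_counts(1326, 213, 149),
                                 gold_total = 1475))
  expect_false(check_conservation(confusion_counts(1365, 583, 62),
                                  gold_total = 1475))
})
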