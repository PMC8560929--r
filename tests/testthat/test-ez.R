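test_that("onset detection scans for the first threshold crossing", {
  X <- rbind(c(1, 2, 3),          # starts above: onset at the first sample
             c(-1, -0.5, 0.2),    # crosses between samples 2 and 3
             c(-1, -1, -1))       # never crosses
  on <- detect_onsets(X, times = c(10, 20, 30), threshold = 0)
  expect_equal(on, c(10, 30, NA))
  expect_error(detect_onsets(matrix(numeric(0), 1, 0)), "empty")
  expect_error(detect_onsets(matrix(NaN, 1, 2)), "finite")
})

test_that("the onset-tolerance rule partitions regions as printed", {
  on <- c(A = 5, B = 12, C = 40, D = NA)
  rep <- classify_regions(on, t_epsilon = 10)
  expect_equal(rep$ez, c(1, 2))
  expect_equal(rep$pz, 3)
  expect_equal(rep$not_recruited, 4)
  expect_equal(rep$t_lambda, 5)
  # degenerate tolerance keeps only the argmin
  expect_equal(classify_regions(on, t_epsilon = 0)$ez, 1)
  # infinite tolerance absorbs every recruited region into the EZ
  rep_inf <- classify_regions(on, t_epsilon = 1e9)
  expect_equal(rep_inf$ez, 1:3)
  expect_length(rep_inf$pz, 0)
  # no onsets at all: everything not recruited, undefined t_lambda
  rep_none <- classify_regions(c(NA, NA), t_epsilon = 10)
  expect_equal(rep_none$not_recruited, 1:2)
  expect_true(is.na(rep_none$t_lambda))
})

test_that("classification invariants hold on random onset maps", {
  withr::with_seed(7, {
    for (k in 1:50) {
      n <- sample(3:12, 1)
      on <- ifelse(runif(n) < 0.3, NA, runif(n, 0, 100))
      te <- runif(1, 0, 30)
      rep <- classify_regions(on, t_epsilon = te)
      # labels partition the regions
      expect_equal(sort(c(rep$ez, rep$pz, rep$not_recruited)), 1:n)
      if (any(!is.na(on))) {
        # the earliest-onset region is always EZ
        expect_true(which.min(on) %in% rep$ez)
        expect_true(all(on[rep$ez] <= rep$t_lambda + te))
        expect_true(all(on[rep$pz] > rep$t_lambda + te))
        expect_true(all(is.na(on[rep$not_recruited])))
      }
    }
  })
})

test_that("recall is non-decreasing in the onset tolerance", {
  withr::with_seed(8, {
    on <- c(runif(8, 0, 80), NA, NA)
    hyp <- c(1, 3, 5, 9)
    recalls <- sapply(seq(0, 80, by = 5), function(te) {
      precision_recall(classify_regions(on, te), hyp)[["recall"]]
    })
  })
  expect_true(all(diff(recalls) >= 0))
})

test_that("precision and recall follow the set arithmetic", {
  pr <- precision_recall(list(c(1, 2)), list(c(1, 3)))
  expect_equal(unname(pr), c(0.5, 0.5))
  expect_equal(unname(precision_recall(list(c(4, 7)), list(c(4, 7)))),
               c(1, 1))
  # pooled counts: (1/2, 1/2) and (3/3, 3/4) pool to 4/5 and 4/6
  pr_pool <- precision_recall(list(c(1, 2), c(4, 5, 6)),
                              list(c(1, 9), c(4, 5, 6, 7)))
  expect_equal(unname(pr_pool), c(4 / 5, 4 / 6))
  per <- precision_recall(list(c(1, 2), c(4, 5, 6)),
                          list(c(1, 9), c(4, 5, 6, 7)),
                          mode = "per_patient")
  expect_equal(per$precision, c(1 / 2, 1))
  expect_equal(per$recall, c(1 / 2, 3 / 4))
  # empty prediction: precision undefined, recall zero
  pr_empty <- precision_recall(list(integer(0)), list(c(1, 2)))
  expect_true(is.na(pr_empty[["precision"]]))
  expect_equal(pr_empty[["recall"]], 0)
})

test_that("the 3-class confusion matrix normalizes within columns", {
  rep1 <- classify_regions(c(5, NA, NA), t_epsilon = 10)
  conf <- confusion_3class(rep1, c(1))
  expect_equal(unname(conf$percent[, "in_hypothesis"]), c(100, 0, 0))
  # hypothesis {A, B}, model EZ {A}, PZ {B}
  rep2 <- classify_regions(c(5, 40, NA), t_epsilon = 10)
  conf2 <- confusion_3class(rep2, c(1, 2))
  expect_equal(unname(conf2$percent[, "in_hypothesis"]), c(50, 50, 0))
  expect_equal(sum(conf2$counts), 3)
  expect_equal(colSums(conf2$percent), c(in_hypothesis = 100,
                                         not_in_hypothesis = 100))
})

test_that("degenerate robustness inputs return empty tables", {
  fx <- reduced_dataset(seed = 1)
  out <- snr_robustness(fx$ds, fx$net$connectome, snr_grid = c(1, 2),
                        n_replicates = 0)
  expect_equal(nrow(out$table), 0)
  expect_true(is.na(out$critical_snr))
})

test_that("the critical-level rule picks the transition midpoint", {
  expect_equal(vepmap:::critical_level(c(1, 2, 3), c(FALSE, TRUE, TRUE)), 1.5)
  expect_equal(vepmap:::critical_level(c(1, 2, 3), c(TRUE, TRUE, TRUE)), 1)
  expect_equal(vepmap:::critical_level(c(1, 2, 3), c(TRUE, FALSE, TRUE)), 2.5)
  expect_identical(vepmap:::critical_level(c(1, 2), c(TRUE, FALSE)), Inf)
})
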