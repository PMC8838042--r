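test_that("confusion counts match a brute-force per-pixel oracle", {
  pred <- matrix(c(1, 1, 0, 1), 2)   # column-major: [[1,0],[1,1]]
  truth <- matrix(c(1, 0, 1, 1), 2)  # [[1,1],[0,1]]
  cc <- confusion_counts(pred, truth)
  expect_equal(unlist(cc[, c("tp", "fp", "fn", "tn")]),
               c(tp = 2, fp = 1, fn = 1, tn = 0))

  set.seed(42)
  for (i in 1:50) {
    p <- random_mask(16, 16, runif(1, 0.1, 0.9))
    t <- random_mask(16, 16, runif(1, 0.1, 0.9))
    got <- confusion_counts(p, t)
    want <- brute_confusion(p, t)
    expect_equal(as.list(got[, c("tp", "fp", "fn", "tn")]), want)
    expect_equal(got$tp + got$fp + got$fn + got$tn, 256)
  }
})

test_that("identity and complement mask pairs give the closed-form counts", {
  set.seed(7)
  m <- random_mask(12, 12, 0.4)
  k <- sum(m)
  same <- confusion_counts(m, m)
  expect_equal(unlist(same[, 1:4]), c(tp = k, fp = 0, fn = 0, tn = 144 - k))
  opp <- confusion_counts(1 - m, m)
  expect_equal(unlist(opp[, 1:4]), c(tp = 0, fp = 144 - k, fn = k, tn = 0))
})

test_that("shape and value validation reject malformed masks", {
  expect_error(confusion_counts(matrix(0, 2, 3), matrix(0, 3, 2)),
               "2x3.*3x2")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               "not binary.*0.5")
})

test_that("scores reproduce the half-overlap example and standard formulas", {
  r <- overlap_scores(list(tp = 4, fp = 4, fn = 4, tn = 4))
  expect_equal(r$jaccard, 1 / 3)
  expect_equal(r$dice, 1 / 2)
  expect_equal(r$precision, 1 / 2)
  expect_equal(r$recall, 1 / 2)
  expect_equal(r$accuracy, 1 / 2)

  perfect <- overlap_scores(confusion_counts(matrix(1, 3, 3), matrix(1, 3, 3)))
  expect_true(all(unlist(perfect[, 1:5]) == 1))

  empty <- overlap_scores(list(tp = 0, fp = 0, fn = 0, tn = 50))
  expect_equal(empty$jaccard, 1)
  expect_equal(empty$dice, 1)
  expect_equal(empty$accuracy, 1)
  expect_true(empty$flagged)
  expect_true(is.na(empty$precision))

  expect_error(overlap_scores(list(tp = 1, fp = 0, fn = 0, tn = 0),
                              smooth = -1), "non-negative")
})

test_that("Dice-Jaccard identity holds over 1000 random mask pairs", {
  set.seed(11)
  for (i in 1:1000) {
    c <- confusion_counts(random_mask(8, 8), random_mask(8, 8))
    if (c$tp + c$fp + c$fn == 0) next
    r <- overlap_scores(c)
    expect_equal(r$dice, 2 * r$jaccard / (1 + r$jaccard), tolerance = 1e-12)
    expect_gte(r$dice, r$jaccard)
  }
})

test_that("adding a correct lesion pixel never decreases overlap scores", {
  set.seed(13)
  for (rep in 1:30) {
    truth <- random_mask(10, 10, 0.5)
    pred <- truth * random_mask(10, 10, 0.6)   # predictions miss some lesion
    missed <- which(truth == 1 & pred == 0)
    if (length(missed) == 0) next
    before <- overlap_scores(confusion_counts(pred, truth))
    pred2 <- pred
    pred2[missed[1]] <- 1
    after <- overlap_scores(confusion_counts(pred2, truth))
    expect_gte(after$jaccard, before$jaccard)
    expect_gte(after$dice, before$dice)
    expect_gte(after$recall, before$recall)
  }
})

test_that("soft overlap matches closed forms and reduces to hard scores", {
  n <- 36
  truth <- matrix(1, 6, 6)
  half <- matrix(0.5, 6, 6)
  s <- soft_overlap(half, truth)
  expect_equal(s$soft_dice, 2 / 3)
  expect_equal(s$soft_jaccard, 1 / 2)

  expect_equal(unlist(soft_overlap(truth, truth)),
               c(soft_jaccard = 1, soft_dice = 1))

  set.seed(3)
  p <- random_mask(9, 9)
  t <- random_mask(9, 9)
  hard <- overlap_scores(confusion_counts(p, t))
  soft <- soft_overlap(p, t)
  expect_equal(soft$soft_jaccard, hard$jaccard)
  expect_equal(soft$soft_dice, hard$dice)

  expect_error(soft_overlap(matrix(1.5, 2, 2), matrix(1, 2, 2)), "\\[0, 1\\]")
})

test_that("evaluate_split with the mask oracle is perfect on synthetic data", {
  ds <- generate_dataset(5, small_synth_cfg(seed = 21))
  lookup <- function(img) {
    for (p in ds$pairs) if (identical(p$image, img)) return(p$mask)
    stop("unknown image")
  }
  m <- evaluate_split(ds$pairs, lookup)
  expect_equal(m$accuracy, 100)
  expect_equal(m$dice, 100)
  expect_equal(m$jaccard, 100)
  expect_lt(m$loss, 1e-4)
})

test_that("constant-0.5 predictor yields the ln(2) cross-entropy bound", {
  pair <- square_pair(32, 32)
  m <- evaluate_split(list(pair), function(img) matrix(0.5, 32, 32))
  expect_equal(m$loss, 100 * log(2), tolerance = 1e-6)
})

test_that("global-pixel aggregation equals scores on summed counts", {
  ds <- generate_dataset(4, small_synth_cfg(seed = 33))
  # a deliberately imperfect predictor: erode by shifting one pixel
  shifty <- function(img) {
    h <- dim(img)[1]; w <- dim(img)[2]
    m <- matrix(0, h, w)
    m[2:h, ] <- (0.6 * (img[1:(h - 1), , 1] < 0.45))
    m
  }
  both <- lapply(ds$pairs, function(p)
    confusion_counts(1 * (shifty(p$image) >= 0.5), p$mask))
  summed <- list(tp = sum(sapply(both, `[[`, "tp")),
                 fp = sum(sapply(both, `[[`, "fp")),
                 fn = sum(sapply(both, `[[`, "fn")),
                 tn = sum(sapply(both, `[[`, "tn")))
  manual <- overlap_scores(summed)
  got <- evaluate_split(ds$pairs, shifty, aggregation = "global_pixels")
  expect_equal(got$jaccard, 100 * manual$jaccard)
  expect_equal(got$dice, 100 * manual$dice)
  expect_equal(got$accuracy, 100 * manual$accuracy)

  # the two aggregation modes coincide when every image has equal counts
  same <- evaluate_split(list(ds$pairs[[1]], ds$pairs[[1]]),
                         function(img) 0.9 * ds$pairs[[1]]$mask)
  same_g <- evaluate_split(list(ds$pairs[[1]], ds$pairs[[1]]),
                           function(img) 0.9 * ds$pairs[[1]]$mask,
                           aggregation = "global_pixels")
  expect_equal(same[, 1:6], same_g[, 1:6])
})

test_that("evaluate_split rejects an empty list", {
  expect_error(evaluate_split(list(), function(img) img), "empty")
})

test_that("metric rows serialize in the reporting column order", {
  rows <- tibble::tibble(split = "validation", optimizer = "adam",
                         batch_size = 8L, epochs = 10L,
                         jaccard = 90, dice = 85, precision = 88,
                         recall = 92, accuracy = 95, loss = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_rows(rows, path)
  got <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(got)[1:4], c("split", "optimizer", "batch_size", "epochs"))
  expect_equal(names(got)[5:10],
               c("jaccard", "dice", "precision", "recall", "accuracy", "loss"))
})
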