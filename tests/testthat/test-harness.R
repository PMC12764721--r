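# fold construction, metrics against brute-force oracles, combined loss

test_that("metrics agree exactly with brute-force counting on random inputs", {
  set.seed(60)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    S <- matrix(rbinom(n * n, 1, runif(1)), n, n)
    T_ <- matrix(rbinom(n * n, 1, runif(1)), n, n)
    got <- segmentation_metrics(S, T_)
    bf <- brute_overlap(S, T_)
    if (bf["s"] == 0 && bf["t"] == 0) {
      expect_equal(unname(got), c(1, 1, 1, 1))
    } else {
      expect_identical(unname(got["dsc"]), 2 * bf[["inter"]] / (bf[["s"]] + bf[["t"]]))
      expect_identical(unname(got["iou"]), bf[["inter"]] / bf[["union"]])
      expect_identical(unname(got["precision"]),
                       if (bf[["s"]] > 0) bf[["inter"]] / bf[["s"]] else 0)
      expect_identical(unname(got["recall"]),
                       if (bf[["t"]] > 0) bf[["inter"]] / bf[["t"]] else 0)
    }
    m <- sample(4:30, 1)
    pred <- rbinom(m, 1, runif(1)); truth <- rbinom(m, 1, runif(1))
    cm <- brute_confusion(pred, truth)
    gotc <- classification_metrics(pred, truth)
    expect_identical(unname(gotc["accuracy"]), (cm[["tp"]] + cm[["tn"]]) / m)
    prec <- if (cm[["tp"]] + cm[["fp"]] > 0) cm[["tp"]] / (cm[["tp"]] + cm[["fp"]]) else 0
    rec <- if (cm[["tp"]] + cm[["fn"]] > 0) cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]) else 0
    expect_identical(unname(gotc["precision"]), prec)
    expect_identical(unname(gotc["recall"]), rec)
    expect_identical(unname(gotc["f1"]),
                     if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  }
})

test_that("metric edge cases follow their definitions", {
  S <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(unname(segmentation_metrics(S, S)), c(1, 1, 1, 1))
  D <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(unname(segmentation_metrics(S, D)), c(0, 0, 0, 0))
  # the printed half-overlap example: |S|=|T|=4, |S.T|=2
  S2 <- matrix(0, 4, 4); S2[1:2, 1:2] <- 1
  T2 <- matrix(0, 4, 4); T2[1:2, 2:3] <- 1
  got <- segmentation_metrics(S2, T2)
  expect_equal(unname(got), c(0.5, 1 / 3, 0.5, 0.5))
  expect_error(segmentation_metrics(S2, matrix(0, 2, 2)), "shapes")
  # classification: TP=3 FP=1 FN=1 TN=5
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  truth <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  expect_equal(unname(classification_metrics(pred, truth)),
               c(0.8, 0.75, 0.75, 0.75))
  expect_equal(unname(classification_metrics(rep(0, 4), c(1, 1, 0, 0))["recall"]), 0)
  expect_error(classification_metrics(integer(0), integer(0)), "nonempty")
})

test_that("fold plans are disjoint, covering, and stratified", {
  recs <- tiny_cohort(n_dm = 24, n_cg = 10, size = 64, seed = 80)
  plan <- make_folds(recs, k = 5, seed = 2)
  a <- plan$assignments
  expect_equal(sort(unique(a$fold)), 1:5)
  expect_equal(nrow(a), 34)
  expect_equal(anyDuplicated(a$subject_code), 0)
  cohort_frac <- 24 / 34
  for (f in 1:5) {
    sub <- a[a$fold == f, ]
    expect_lte(abs(mean(sub$group == "DM") - cohort_frac), 1 / nrow(sub))
  }
  # record-level split: union of test folds covers all records disjointly
  seen <- integer(0)
  for (f in 1:5) {
    sp <- fold_split(plan, recs, f)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(intersect(seen, sp$test), 0)
    seen <- c(seen, sp$test)
  }
  expect_setequal(seen, seq_along(recs))
  # every subject appears in exactly k-1 training folds
  trains <- sapply(1:5, function(f)
    length(fold_split(plan, recs, f)$train))
  expect_equal(sum(trains), 4 * length(recs))
  expect_error(make_folds(tiny_cohort(n_dm = 6, n_cg = 3, seed = 1), k = 5),
               "fewer than")
})

test_that("the study-scale cohort partitions into balanced folds", {
  # subject-level integer partition for 122 DM + 45 CG into 5 folds
  subj <- data.frame(
    subject_code = sprintf("%03d", 1:167),
    group = rep(c("DM", "CG"), c(122, 45)))
  recs <- lapply(seq_len(nrow(subj)), function(i)
    thermogram_record(list(subject_code = subj$subject_code[i],
                           group = subj$group[i], gender = "F",
                           side = "left"),
                      matrix(0.5, 8, 8)))
  plan <- make_folds(recs, k = 5, seed = 3)
  a <- plan$assignments
  sizes <- table(a$fold)
  expect_true(all(sizes %in% 33:34))
  dm <- table(a$fold[a$group == "DM"])
  cg <- table(a$fold[a$group == "CG"])
  expect_true(all(dm %in% 24:25))
  expect_true(all(cg == 9))
})

test_that("augmented copies follow their source subject's fold", {
  recs <- tiny_cohort(n_dm = 6, n_cg = 5, seed = 81)
  plan <- make_folds(recs, k = 5, seed = 4)
  aug <- unlist(lapply(recs, augment,
                       spec = augment_spec(copies_per_image = 2, seed = 5)),
                recursive = FALSE)
  all_recs <- c(recs, aug)
  for (f in 1:5) {
    sp <- fold_split(plan, all_recs, f)
    test_subj <- unique(vapply(all_recs[sp$test],
                               function(r) r$meta$subject_code, character(1)))
    train_subj <- unique(vapply(all_recs[sp$train],
                                function(r) r$meta$subject_code, character(1)))
    expect_length(intersect(test_subj, train_subj), 0)
  }
})

test_that("combined loss is the stated affine mix of its components", {
  set.seed(62)
  lg <- array(rnorm(2 * 8 * 8 * 2), c(2, 8, 8, 2))
  mk <- array(rbinom(2 * 64, 1, 0.2), c(2, 8, 8))
  Y <- diag(2)[c(1, 2), ]
  unif <- matrix(0.5, 2, 2)
  dl <- dice_loss(lg, mk)
  expect_equal(combined_loss(lg, mk, unif, Y, alpha = 1, beta = 0), dl)
  expect_equal(combined_loss(lg, mk, unif, Y, alpha = 0.6, beta = 0.4),
               0.6 * dl + 0.4 * log(2))
  # affine in both components over a grid of weights
  for (w in list(c(0.3, 0.7), c(0.5, 0.5), c(0.9, 0.1)))
    expect_equal(combined_loss(lg, mk, unif, Y, w[1], w[2]),
                 w[1] * dl + w[2] * log(2))
  # perfect segmentation + perfect classification -> 0
  perfect <- array(0, c(2, 8, 8, 2))
  perfect[, , , 2] <- ifelse(mk == 1, 50, -50)
  perfect[, , , 1] <- -perfect[, , , 2]
  exactY <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_lt(combined_loss(perfect, mk, exactY, c(0L, 1L)), 1e-3)
})

test_that("early stopping with zero patience halts after one stall", {
  recs <- tiny_cohort(n_dm = 6, n_cg = 5, size = 64, seed = 82)
  # layer norm keeps the validation loss frozen at negligible lr (batch norm
  # running statistics would keep drifting it)
  m <- tiny_model(embed = 16, norm = "layer_norm")
  cfg <- train_config(lr = 1e-12, epochs_max = 10, batch_size = 8,
                      early_stop_patience = 0, seed = 3)
  # negligible lr: the validation loss cannot improve by min_delta
  fit <- train_model(m, recs, cfg)
  expect_equal(nrow(fit$history), 2)
  # the best-so-far bookkeeping is monotone
  expect_true(all(diff(cummin(fit$history$val_loss)) <= 0))
})
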