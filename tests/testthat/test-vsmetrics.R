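rl <- function(scores, labels, clusters = NULL) {
  ranked_list(seq_along(scores), scores, labels, clusters)
}

test_that("ROC curve hits the corners for perfect and inverted rankings", {
  perfect <- rl(c(4, 3, 2, 1), c("active", "active", "decoy", "decoy"))
  rc <- roc_curve(perfect)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))
  expect_equal(rc[nrow(rc), ], data.frame(fpr = 1, tpr = 1),
               ignore_attr = TRUE)
  inverted <- rl(c(4, 3, 2, 1), c("decoy", "decoy", "active", "active"))
  ri <- roc_curve(inverted)
  expect_true(any(ri$fpr == 1 & ri$tpr == 0))
})

test_that("ROC curve enumerates thresholds on the worked example", {
  r <- rl(c(4, 3, 2, 1), c("active", "decoy", "active", "decoy"))
  rc <- roc_curve(r)
  expect_true(all(c(TRUE) %in% (rc$fpr == 0 & rc$tpr == 0.5)))
  expect_true(any(rc$fpr == 0.5 & rc$tpr == 1))
  expect_error(roc_curve(rl(c(1, 2), c("active", "active"))),
               "at least one")
})

test_that("AUC matches hand-computed and degenerate cases", {
  expect_equal(auc(rl(c(4, 3, 2, 1), c("active", "active", "decoy", "decoy"))), 1)
  expect_equal(auc(rl(rep(1, 6), c("active", "decoy", "active",
                                   "decoy", "decoy", "active"))), 0.5)
  expect_equal(auc(rl(c(4, 3, 2, 1), c("active", "decoy", "active", "decoy"))),
               0.75)
})

test_that("AUC equals the Mann-Whitney pair-count oracle with ties", {
  set.seed(7)
  for (k in 1:300) {
    n <- sample(5:40, 1)
    scores <- sample(round(runif(n), 2))      # rounded to force ties
    labels <- sample(c("active", "decoy"), n, replace = TRUE)
    if (!any(labels == "active") || !any(labels == "decoy")) next
    r <- rl(scores, labels)
    expect_equal(auc(r), mw_auc(r$score, r$label == "active"),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- runif(60)
  labels <- sample(c("active", "decoy"), 60, replace = TRUE, prob = c(.3, .7))
  r <- rl(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("decoy", "active"),
    direction = "<", quiet = TRUE)))
  expect_equal(auc(r), ref, tolerance = 1e-12)
})

test_that("BEDROC attains its closed-form extremes and stays in [0,1]", {
  lab <- c(rep("active", 5), rep("decoy", 45))
  perfect <- rl(seq(50, 1), lab)
  expect_equal(bedroc(perfect), 1, tolerance = 1e-9)
  worst <- rl(seq(50, 1), rev(lab))
  expect_equal(bedroc(worst), 0, tolerance = 1e-9)
  set.seed(9)
  for (k in 1:50) {
    n <- sample(10:60, 1)
    r <- rl(runif(n), sample(c("active", "decoy"), n, replace = TRUE,
                             prob = c(.2, .8)))
    if (!any(r$label == "active") || !any(r$label == "decoy")) next
    b <- bedroc(r, alpha = sample(c(5, 20, 53.6), 1))
    expect_gte(b, 0); expect_lte(b, 1)
  }
})

test_that("BEDROC is invariant to strictly monotone score transforms", {
  set.seed(10)
  scores <- runif(40)
  labels <- sample(c("active", "decoy"), 40, replace = TRUE, prob = c(.25, .75))
  r1 <- rl(scores, labels)
  r2 <- rl(exp(3 * scores) + 7, labels)
  expect_equal(bedroc(r1), bedroc(r2), tolerance = 1e-12)
})

test_that("80% of the BEDROC weight mass lies in the top 3% at alpha 53.6", {
  expect_equal(100 * bedroc_weight_mass(53.6, 0.03), 80, tolerance = 0.5)
})

test_that("ROCE reproduces the worked enrichment arithmetic", {
  # 5 of 20 actives retrieved along with the top 1% of 500 decoys
  set.seed(99)
  labels <- c(rep("active", 5), rep("decoy", 5),
              sample(c(rep("active", 15), rep("decoy", 495))))
  r <- rl(seq(length(labels), 1), labels)
  expect_equal(roce(r, 1), (5 / 20) / 0.01, tolerance = 1e-12)
  # all actives above all decoys: ROCE = 1 / (x/100)
  r2 <- rl(seq(30, 1), c(rep("active", 10), rep("decoy", 20)))
  expect_equal(roce(r2, 10), 10)
  expect_equal(roce(r2, 50), 2)
})

test_that("ROCE of an exchangeable ranking is about 1 and roce*fpr <= 1", {
  set.seed(12)
  vals <- replicate(300, {
    n <- 500
    r <- rl(runif(n), sample(c(rep("active", 50), rep("decoy", 450))))
    roce(r, 10)
  })
  expect_equal(mean(vals), 1, tolerance = 0.1)
  set.seed(13)
  for (k in 1:50) {
    r <- rl(runif(60), sample(c(rep("active", 10), rep("decoy", 50))))
    x <- sample(c(2, 5, 10, 20), 1)
    co_fpr <- ceiling(x / 100 * 50) / 50
    expect_lte(roce(r, x) * co_fpr, 1 + 1e-12)
  }
})

test_that("awROCE reproduces the cluster-weighted worked example", {
  # clusters {1,3}; the singleton and one trio member retrieved before the
  # top-5% decoy cutoff (1 of 20 decoys)
  scores <- seq(24, 1)
  labels <- c("active", "active", rep("decoy", 20), "active", "active")
  clusters <- c("solo", "trio", rep(NA, 20), "trio", "trio")
  r <- rl(scores, labels, clusters)
  expect_equal(awroce(r, 5), ((1 + 1 / 3) / 2) / 0.05, tolerance = 1e-12)
  expect_equal(awroce(r, 5), 13.33, tolerance = 1e-2)
  expect_error(awroce(rl(scores, labels, NULL), 5), "cluster")
})

test_that("awROCE with singleton clusters equals ROCE, and is 0 with no hits", {
  set.seed(14)
  for (k in 1:30) {
    n <- sample(30:80, 1)
    labels <- sample(c("active", "decoy"), n, replace = TRUE, prob = c(.3, .7))
    if (sum(labels == "active") < 2 || sum(labels == "decoy") < 5) next
    clusters <- ifelse(labels == "active",
                       paste0("c", cumsum(labels == "active")), NA)
    r <- rl(runif(n), labels, clusters)
    x <- sample(c(5, 10, 25), 1)
    expect_equal(awroce(r, x), roce(r, x), tolerance = 1e-12)
  }
  nohit <- rl(seq(22, 1), c(rep("decoy", 20), "active", "active"),
              c(rep(NA, 20), "c1", "c1"))
  expect_equal(awroce(nohit, 5), 0)
})

test_that("chemotype discovery curve steps at the decoy fractions of first hits", {
  # 3 clusters discovered at decoy fractions 0.0, 0.1, 0.5 (10 decoys)
  scores <- seq(13, 1)
  labels <- c("active", rep("decoy", 1), "active",
              rep("decoy", 4), "active", rep("decoy", 5))
  clusters <- c("c1", NA, "c2", rep(NA, 4), "c3", rep(NA, 5))
  cv <- chemotype_discovery_curve(rl(scores, labels, clusters))
  expect_equal(cv$decoy_frac, c(0, 0.1, 0.5))
  expect_equal(cv$cluster_frac, c(1, 2, 3) / 3)
  # all clusters before the first decoy
  early <- rl(seq(5, 1), c("active", "active", rep("decoy", 3)),
              c("c1", "c2", NA, NA, NA))
  cve <- chemotype_discovery_curve(early)
  expect_equal(cve$decoy_frac, c(0, 0))
  expect_equal(max(cve$cluster_frac), 1)
  # single cluster is a single step
  single <- rl(seq(4, 1), c("decoy", "active", "active", "decoy"),
               c(NA, "c1", "c1", NA))
  expect_equal(nrow(chemotype_discovery_curve(single)), 1)
})

test_that("metrics are invariant to permuting tied entries", {
  scores <- c(3, 2, 2, 2, 1, 1)
  labels <- c("active", "decoy", "active", "decoy", "active", "decoy")
  clusters <- ifelse(labels == "active", c("c1", NA, "c2", NA, "c1", NA), NA)
  r1 <- ranked_list(1:6, scores, labels, clusters)
  set.seed(15)
  for (k in 1:10) {
    p <- sample(6)
    r2 <- ranked_list(p, scores[p], labels[p], clusters[p])
    expect_equal(auc(r2), auc(r1))
    expect_equal(bedroc(r2), bedroc(r1))
    expect_equal(roce(r2, 40), roce(r1, 40))
    expect_equal(awroce(r2, 40), awroce(r1, 40))
  }
})

test_that("metric reports aggregate and serialize", {
  fx <- small_fixture()
  r <- oa_screen(fx$query, fx$dataset)
  rep1 <- metric_report(r)
  expect_true(all(is.finite(c(rep1$auc, rep1$bedroc, rep1$roce, rep1$awroce))))
  expect_equal(rep1$alpha, 53.6)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep1, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$auc, rep1$auc, tolerance = 1e-12)
  # ranked list round-trip
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_list(r, tmp2)
  r2 <- read_ranked_list(tmp2)
  expect_equal(r2$id, r$id)
  expect_equal(auc(r2), auc(r), tolerance = 1e-9)
})
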