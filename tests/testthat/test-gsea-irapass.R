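test_that("correlation scores follow the signed -log10 p construction", {
  set.seed(1)
  n <- 20
  pd <- toy_pdui(matrix(runif(2 * n, 0.1, 0.9), 2, n))
  ex <- rbind(GSAME = unclass(pd)[1, ],          # identical to event 1 PDUI
              GRAND = rlnorm(n))
  colnames(ex) <- colnames(pd)
  cp <- quiet(correlation_score(expression_table(ex), pd))
  expect_equal(unname(cp$cor["GSAME", 1]), 1)
  expect_equal(unname(cp$cs["GSAME", 1]), 20)    # -log10(0 + 1e-20)
  expect_true(all(abs(cp$cs) <= 20 + 1e-9, na.rm = TRUE))
  # flipping the gene flips CS exactly
  ex2 <- ex; ex2["GRAND", ] <- max(ex["GRAND", ]) - ex["GRAND", ]
  cp2 <- quiet(correlation_score(expression_table(ex2), pd))
  expect_equal(cp2$cs["GRAND", ], -cp$cs["GRAND", ])
  # degenerate constant gene yields missing CS
  ex3 <- rbind(ex, GCONST = rep(2, n))
  cp3 <- quiet(correlation_score(expression_table(ex3), pd))
  expect_true(all(is.na(cp3$cs["GCONST", ])))
})

test_that("GSEA enrichment scores equal the brute-force running-sum oracle", {
  set.seed(11)
  for (rep in 1:8) {
    N <- sample(8:15, 1)
    stat <- setNames(rnorm(N), paste0("g", seq_len(N)))
    set_ <- sample(names(stat), sample(3:min(6, N), 1))
    for (w in c(0, 1)) {
      got <- preranked_gsea(stat, list(S = set_), weight = w, n_perm = 50,
                            min_size = 2)
      expect_equal(got$es, oracle_es(stat, set_, weight = w), tolerance = 1e-12)
    }
  }
  # a set of top-ranked genes recovers the classic KS statistic at weight 0
  stat <- setNames(10:1, paste0("g", 1:10))
  top3 <- paste0("g", 1:3)
  got <- preranked_gsea(stat, list(S = top3), weight = 0, n_perm = 50,
                        min_size = 2)
  expect_equal(got$es, 1)  # 3 hits before any miss: 3 * (1/3)
  expect_warning(
    preranked_gsea(stat, list(ALL = names(stat)), n_perm = 20, min_size = 2),
    "entire universe")
})

test_that("enrichment scores agree with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  for (i in 1:5) {
    set.seed(100 + i)
    stat <- setNames(rnorm(60), paste0("g", 1:60))
    set_ <- sample(names(stat), 10)
    ours <- preranked_gsea(stat, list(S = set_), n_perm = 20, seed = i,
                           min_size = 2)$es
    ranked <- sort(stat, decreasing = TRUE)
    theirs <- fgsea::calcGseaStat(
      ranked, selectedStats = which(names(ranked) %in% set_), gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("GSEA p-values are approximately uniform under the null", {
  set.seed(21)
  stat <- setNames(rnorm(400), paste0("g", 1:400))
  sets <- lapply(1:60, function(i) sample(names(stat), 20))
  names(sets) <- paste0("S", 1:60)
  res <- preranked_gsea(stat, sets, n_perm = 400, seed = 3)
  ks <- suppressWarnings(stats::ks.test(res$perm_p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pathAPAscore implements the piecewise 1-2p / 2p-1 formula", {
  expect_equal(path_apa_score(2.0, 0.0025), 0.995)
  expect_equal(path_apa_score(-2.0, 0.0025), -0.995)
  expect_equal(path_apa_score(1.3, 0.5), 0)
  expect_equal(path_apa_score(-1.3, 0.5), 0)
  expect_equal(path_apa_score(0, 0.2), 0)
  # odd function of (sign(ES), p)
  p <- runif(20, 0.001, 1)
  expect_equal(path_apa_score(-1, p), -path_apa_score(1, p))
  expect_error(path_apa_score(1, 0), "\\(0, 1\\]")
  expect_error(path_apa_score(1, 1.5), "\\(0, 1\\]")
})

test_that("the immune screen applies its three filters in order", {
  mk <- function(nes_r, nes_nr, score_r = 0.999, fdr_r = 0.01) {
    list(responder = data.frame(event_id = "E|chr1|1", pathway = "P",
                                es = sign(nes_r), nes = nes_r, perm_p = 0.001,
                                fdr_q = fdr_r, path_apa_score = score_r),
         nonresponder = data.frame(event_id = "E|chr1|1", pathway = "P",
                                   es = sign(nes_nr), nes = nes_nr,
                                   perm_p = 0.3, fdr_q = 0.6,
                                   path_apa_score = 0.4))
  }
  # opposite NES, strong in responders, consistent across cohorts -> retained
  keep <- screen_immune_events(list(c1 = mk(2.1, -1.8), c2 = mk(1.9, -1.5)))
  expect_equal(keep$events, "E|chr1|1")
  expect_equal(keep$pairs$orientation, 1)
  # same-sign NES dropped at filter 2
  drop2 <- screen_immune_events(list(c1 = mk(2.1, 1.8), c2 = mk(1.9, 1.5)))
  expect_equal(length(drop2$events), 0)
  # below threshold in both groups dropped at filter 1
  drop1 <- screen_immune_events(list(c1 = mk(2.1, -1.8, score_r = 0.9),
                                     c2 = mk(1.9, -1.5, score_r = 0.9)))
  expect_equal(length(drop1$events), 0)
  # orientation flip between cohorts dropped at filter 3
  drop3 <- screen_immune_events(list(c1 = mk(2.1, -1.8), c2 = mk(-1.9, 1.5)))
  expect_equal(length(drop3$events), 0)
  expect_error(screen_immune_events(list(c1 = mk(1, -1))), "two cohorts")
})

test_that("univariate Cox finds the survival-driving feature and skips junk", {
  set.seed(4)
  n <- 120
  latent <- rnorm(n)
  os_time <- rexp(n, 0.002 * exp(-latent))
  os_event <- runif(n) > 0.3
  feats <- cbind(driver = latent + rnorm(n, 0, 0.3),
                 noise = rnorm(n),
                 flat = rep(0.5, n))
  res <- suppressWarnings(univariate_cox(feats, os_time, os_event))
  expect_false("flat" %in% res$feature)
  expect_lt(res$p[res$feature == "driver"], 1e-4)
  expect_lt(res$hr[res$feature == "driver"], 1)  # protective
  expect_error(univariate_cox(feats[1:5, ], os_time[1:5], rep(FALSE, 5)),
               ">= 10")
})

test_that("LASSO Cox keeps informative features and prunes noise", {
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 105
    x <- matrix(rbeta(n * 50, 5, 5), n, 50,
                dimnames = list(NULL, sprintf("f%02d", 1:50)))
    risk <- 3 * (rowSums(x[, 1:5]) - 2.5)
    os_time <- rexp(n, 0.002 * exp(risk))
    os_event <- runif(n) > 0.15
    sel <- quiet(lasso_cox(x, os_time, os_event, seed = s, cv_folds = 10))$selected
    c(sum(sprintf("f%02d", 1:5) %in% sel), sum(!(sel %in% sprintf("f%02d", 1:5))))
  }, numeric(2))
  expect_gte(median(aucs[1, ]), 3)   # informative kept
  expect_lte(median(aucs[2, ]), 5)   # noise mostly pruned
  # duplicated features are not both selected with equal nonzero weight
  set.seed(2)
  x <- matrix(rbeta(100 * 2, 5, 5), 100, 2)
  x <- cbind(a = x[, 1], b = x[, 1], c = x[, 2])
  os_time <- rexp(100, 0.002 * exp(2 * x[, 1]))
  res <- quiet(lasso_cox(x, os_time, rep(TRUE, 100), seed = 1))
  co <- res$coefficients
  expect_false(isTRUE(all(c("a", "b") %in% names(co)) &&
                        abs(co["a"] - co["b"]) < 1e-12 && co["a"] != 0))
})

test_that("the linear scorer separates, reproduces, and recovers weights", {
  set.seed(6)
  n <- 200
  x <- matrix(rbeta(n * 4, 4, 4), n, 4,
              dimnames = list(sprintf("s%03d", 1:n),
                              sprintf("E%d|chr1|%d", 1:4, 1:4)))
  w <- c(2.5, -1.8, 1.2, -0.6)
  lin <- drop(x %*% w)
  resp <- ifelse(lin + rnorm(n, 0, 0.1) > median(lin), "PRCR", "PDSD")
  m1 <- quiet(fit_scorer(x, resp, split = 0.7, seed = 3))
  m2 <- quiet(fit_scorer(x, resp, split = 0.7, seed = 3))
  expect_identical(m1$coefficients, m2$coefficients)   # seed-fixed refit
  sc <- irapass_score(m1, t(x))
  tr <- m1$metadata$train_idx
  ev <- evaluate_scores(sc[tr], resp[tr])
  expect_gt(ev$auc, 0.97)
  cosine <- sum(m1$coefficients * w) /
    sqrt(sum(m1$coefficients^2) * sum(w^2))
  expect_gte(cosine, 0.9)
  expect_error(fit_scorer(x[1:8, ], resp[1:8]), "training samples")
})

test_that("scoring is an exact linear form over PDUI features", {
  m <- irapass_model(c("A|chr1|1", "B|chr2|2"), c(2, -3), intercept = 0.5)
  x <- setNames(c(0.4, 0.6), m$features)
  y <- setNames(c(0.1, 0.9), m$features)
  sx <- irapass_score(m, x); sy <- irapass_score(m, y)
  a <- 1.7; b <- -0.4
  expect_equal(unname(irapass_score(m, a * x + b * y)),
               unname(a * sx + b * sy - (a + b - 1) * m$intercept))
  expect_error(irapass_score(m, setNames(0.5, "A|chr1|1")), "absent")
  expect_equal(unname(irapass_score(m, setNames(c(0, 0), m$features))), 0.5)
})

test_that("the packaged published model scores by its printed coefficients", {
  m <- published_irapass_model()
  expect_length(m$features, 10)
  expect_equal(m$intercept, 0)
  for (f in m$features) {
    v <- setNames(numeric(10), m$features)
    v[f] <- 1
    expect_equal(unname(irapass_score(m, v)), unname(m$coefficients[f]))
  }
  expect_equal(unname(irapass_score(m, setNames(numeric(10), m$features))), 0)
})

test_that("score evaluation reports honest AUC and survival contrasts", {
  set.seed(9)
  resp <- rep(c("PRCR", "PDSD"), c(30, 70))
  sc <- setNames(as.numeric(resp == "PRCR"), sprintf("s%03d", 1:100))
  ev <- evaluate_scores(sc, resp)
  expect_equal(ev$auc, 1)
  null_auc <- vapply(1:25, function(i)
    evaluate_scores(setNames(sample(sc), names(sc)), resp)$auc, numeric(1))
  expect_lt(abs(mean(null_auc) - 0.5), 0.06)
  expect_warning(evaluate_scores(sc[1:30], resp[1:30]), "single response")
  # survival: protective high score separates the KM curves
  lat <- rnorm(100) + 2 * (resp == "PRCR")
  os_time <- rexp(100, 0.002 * exp(-lat))
  ev2 <- evaluate_scores(sc + rnorm(100, 0, 0.2), resp, os_time,
                         rep(TRUE, 100))
  expect_lt(ev2$logrank_p, 0.05)
  expect_true(!is.null(ev2$cox))
})

test_that("the MLP architecture exposes an equivalent-linear export", {
  set.seed(12)
  n <- 150
  x <- matrix(rbeta(n * 3, 4, 4), n, 3,
              dimnames = list(NULL, sprintf("E%d|chr1|%d", 1:3, 1:3)))
  resp <- ifelse(x[, 1] - x[, 2] + rnorm(n, 0, 0.2) > 0, "PRCR", "PDSD")
  m <- quiet(fit_scorer(x, resp, architecture = "mlp", seed = 5))
  expect_s3_class(m, "irapass_model")
  expect_length(m$coefficients, 3)
  fit <- m$metadata$nnet_fit
  # strict export refuses when the hidden layer carries real weight
  hid <- fit$wts[((fit$n[1] + 1) * fit$n[2] + 2):((fit$n[1] + 1) * fit$n[2] + 1 + fit$n[2])]
  if (max(abs(hid)) > 1e-6)
    expect_error(linear_export(fit, colnames(x)), "hidden layer")
})
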