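#' Correlation-score (CS) profile between gene expression and event PDUI
#'
#' For every (gene, event) pair, the Pearson correlation `Cor` of the gene's
#' expression with the event's PDUI over the chosen samples yields a
#' two-sided p-value `P`, and
#' `CS = -log10(P + 1e-20) * sign(Cor)`,
#' so `|CS| <= 20` and the sign tracks the correlation direction. Pairs with
#' fewer than `min_obs` pairwise-complete observations, or a constant vector,
#' get missing CS.
#'
#' @param expr an [expression_table()] (genes x samples).
#' @param pdui a [pdui_table()] (events x samples).
#' @param samples optional sample subset (default: all shared samples).
#' @param min_obs minimum pairwise-complete observations (default 5).
#' @return list of class `cs_profile` with matrices `cs`, `cor`, `p`
#'   (genes x events) and `n_samples`.
#' @export
correlation_score <- function(expr, pdui, samples = NULL, min_obs = 5) {
  shared <- align_samples(colnames(expr), colnames(pdui))
  if (!is.null(samples)) shared <- shared[shared %in% samples]
  if (length(shared) < min_obs) stop("need >= ", min_obs, " shared samples")
  X <- t(unclass(expr)[, shared, drop = FALSE])   # samples x genes
  Y <- t(unclass(pdui)[, shared, drop = FALSE])   # samples x events
  n_pair <- crossprod(!is.na(X) * 1, !is.na(Y) * 1)
  suppressWarnings(
    r <- cor(X, Y, use = "pairwise.complete.obs"))
  r[n_pair < min_obs] <- NA_real_
  df <- n_pair - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-abs(tstat), pmax(df, 1))
  p[abs(r) >= 1 - 1e-12] <- 0     # perfect correlation underflows
  cs <- -log10(p + 1e-20) * sign(r)
  structure(list(cs = cs, cor = r, p = p, n_samples = length(shared)),
            class = "cs_profile")
}

#' Event-pathway association tables for one sample group
#'
#' Runs [preranked_gsea()] on the CS column of every event of a
#' [correlation_score()] profile.
#'
#' @param cs_profile a `cs_profile`.
#' @param gene_sets a [gene_set_collection()].
#' @inheritParams preranked_gsea
#' @return data.frame with columns event_id, pathway, size, es, nes, perm_p,
#'   fdr_q, path_apa_score (FDR is per event, across pathways).
#' @export
event_pathway_associations <- function(cs_profile, gene_sets, weight = 1,
                                       n_perm = 1000, seed = 1, min_size = 5) {
  events <- colnames(cs_profile$cs)
  res <- lapply(events, function(ev) {
    stat <- cs_profile$cs[, ev]
    stat <- stat[!is.na(stat)]
    if (length(stat) < min_size) return(NULL)
    g <- preranked_gsea(stat, gene_sets, weight = weight, n_perm = n_perm,
                        seed = seed, min_size = min_size)
    if (!nrow(g)) return(NULL)
    cbind(event_id = ev, g, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Screen immune-associated APA events across groups and cohorts
#'
#' Applies the three sequential filters of the scoring-system construction:
#' (1) an event-pathway pair must reach `|pathAPAscore| > score_threshold`
#' with `fdr_q < fdr_threshold` in at least one response group;
#' (2) its NES must have opposite signs in responders vs non-responders;
#' (3) the pair must survive (1)+(2) in both cohorts with the same
#' orientation (the sign of the responder NES).
#'
#' @param associations nested list
#'   `associations[[cohort]][[group]]` = association data.frame from
#'   [event_pathway_associations()], with groups named `"responder"` and
#'   `"nonresponder"`, for exactly two cohorts.
#' @param score_threshold pathAPAscore magnitude cutoff (default 0.995,
#'   strict `>`).
#' @param fdr_threshold FDR cutoff (default 0.05, strict `<`).
#' @return list with `pairs` (event_id, pathway, orientation) and `events`
#'   (unique surviving event ids).
#' @export
screen_immune_events <- function(associations, score_threshold = 0.995,
                                 fdr_threshold = 0.05) {
  if (length(associations) != 2)
    stop("need association tables for exactly two cohorts")
  per_cohort <- lapply(associations, function(coh) {
    if (!all(c("responder", "nonresponder") %in% names(coh)))
      stop("each cohort needs 'responder' and 'nonresponder' tables")
    r <- coh$responder; nr <- coh$nonresponder
    if (is.null(r) || is.null(nr)) stop("missing association table")
    m <- merge(r, nr, by = c("event_id", "pathway"),
               suffixes = c("_r", "_nr"))
    pass1 <- (abs(m$path_apa_score_r) > score_threshold & m$fdr_q_r < fdr_threshold) |
             (abs(m$path_apa_score_nr) > score_threshold & m$fdr_q_nr < fdr_threshold)
    pass2 <- !is.na(m$nes_r) & !is.na(m$nes_nr) & (m$nes_r * m$nes_nr < 0)
    m <- m[pass1 & pass2, , drop = FALSE]
    data.frame(event_id = m$event_id, pathway = m$pathway,
               orientation = sign(m$nes_r), stringsAsFactors = FALSE)
  })
  key <- function(d) paste(d$event_id, d$pathway, d$orientation, sep = "\r")
  shared <- intersect(key(per_cohort[[1]]), key(per_cohort[[2]]))
  pairs <- per_cohort[[1]][key(per_cohort[[1]]) %in% shared, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, events = unique(pairs$event_id))
}

#' Univariate Cox screen of PDUI features
#'
#' Fits one proportional-hazards model per feature (standardized to zero
#' mean, unit variance; missing values mean-imputed before standardization)
#' and reports the Wald p-value and hazard ratio. Features that are constant
#' or fail to converge are skipped with a warning.
#'
#' @param features samples x features numeric matrix (raw PDUI).
#' @param os_time,os_event survival outcome (days; event indicator).
#' @param p_threshold pass cutoff (default 0.05).
#' @param min_events minimum number of deaths required (default 10).
#' @return data.frame feature, hr, p, passed.
#' @export
univariate_cox <- function(features, os_time, os_event, p_threshold = 0.05,
                           min_events = 10) {
  features <- as.matrix(features)
  if (sum(os_event, na.rm = TRUE) < min_events)
    stop("need >= ", min_events, " observed events for Cox screening")
  y <- survival::Surv(os_time, os_event)
  out <- lapply(colnames(features), function(f) {
    x <- features[, f]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (sd(x) == 0) {
      warning("constant feature skipped: ", f)
      return(NULL)
    }
    x <- (x - mean(x)) / sd(x)
    fit <- tryCatch(survival::coxph(y ~ x), error = function(e) NULL,
                    warning = function(w) suppressWarnings(survival::coxph(y ~ x)))
    if (is.null(fit) || is.na(coef(fit))) {
      warning("Cox fit failed for feature: ", f)
      return(NULL)
    }
    s <- summary(fit)$coefficients
    data.frame(feature = f, hr = s[1, "exp(coef)"], p = s[1, "Pr(>|z|)"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(feature = character(), hr = numeric(),
                                      p = numeric())
  out$passed <- out$p < p_threshold
  rownames(out) <- NULL
  out
}

#' LASSO Cox feature selection
#'
#' L1-penalized proportional-hazards regression over a logarithmic penalty
#' path; the penalty is chosen by cross-validated partial likelihood at the
#' 1-SE rule, falling back to the CV-minimum penalty (with a warning) when
#' the 1-SE model is empty. Features are standardized internally.
#'
#' @param features samples x features matrix (>= 2 features).
#' @param os_time,os_event survival outcome.
#' @param cv_folds cross-validation folds (default 5).
#' @param seed RNG seed (fold assignment).
#' @return list with `selected` (feature names with nonzero coefficients),
#'   `coefficients` (on the standardized scale) and `lambda`.
#' @export
lasso_cox <- function(features, os_time, os_event, cv_folds = 5, seed = 1) {
  features <- as.matrix(features)
  if (ncol(features) < 2) stop("LASSO Cox needs >= 2 features")
  x <- apply(features, 2, function(v) {
    v[is.na(v)] <- mean(v, na.rm = TRUE); v
  })
  y <- survival::Surv(os_time, os_event)
  set.seed(seed)
  cvfit <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1,
                             nfolds = cv_folds, standardize = TRUE)
  lam <- cvfit$lambda.1se
  co <- as.matrix(coef(cvfit, s = lam))
  if (all(co == 0)) {
    warning("1-SE penalty selects nothing; falling back to CV-minimum penalty")
    lam <- cvfit$lambda.min
    co <- as.matrix(coef(cvfit, s = lam))
  }
  sel <- rownames(co)[co[, 1] != 0]
  list(selected = sel, coefficients = setNames(co[co[, 1] != 0, 1], sel),
       lambda = lam, cv_fit = cvfit)
}

#' Construct an IRAPAss linear scoring model
#'
#' @param features character vector of event ids (unique).
#' @param coefficients numeric vector, same length/order as `features`.
#' @param intercept scalar (default 0; the published model has none).
#' @param metadata free-form list (training seed, split, selection trail...).
#' @return object of class `irapass_model`.
#' @export
irapass_model <- function(features, coefficients, intercept = 0,
                          metadata = list()) {
  features <- as.character(features)
  if (anyDuplicated(features)) stop("duplicate features")
  if (length(features) != length(coefficients))
    stop("features and coefficients lengths differ")
  structure(list(features = features,
                 coefficients = setNames(as.numeric(coefficients), features),
                 intercept = as.numeric(intercept), metadata = metadata),
            class = "irapass_model")
}

#' @method print irapass_model
#' @export
print.irapass_model <- function(x, ...) {
  cat("IRAPAss linear model:", length(x$features), "features, intercept",
      format(x$intercept), "\n")
  print(data.frame(event_id = x$features, coefficient = x$coefficients,
                   row.names = NULL))
  invisible(x)
}

#' The published ten-event IRAPAss model
#'
#' Loads the packaged linear scoring formula (ten APA-event PDUI features,
#' intercept 0) as an [irapass_model()].
#'
#' @return an `irapass_model` with exactly 10 features.
#' @export
published_irapass_model <- function() {
  path <- system.file("extdata", "irapass_published_model.tsv",
                      package = "irapass", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  irapass_model(df$event_id, df$coefficient, intercept = 0,
                metadata = list(source = "published"))
}

#' Train an IRAPAss scorer
#'
#' Randomly splits the samples 70/30 into training and test sets and fits
#' the scoring model on the training portion. The canonical architecture is
#' a single linear layer (logistic link against responder status): the final
#' scoring rule is a plain linear combination of raw PDUI features, matching
#' the published formula's form. Architecture `"mlp"` fits a one-hidden-layer
#' perceptron with skip-layer connections via \pkg{nnet}; its skip weights
#' provide an equivalent-linear export whenever the hidden layer's output
#' weights are negligible (see [linear_export()]).
#'
#' @param features samples x features matrix of raw PDUI values.
#' @param response per-sample labels, `"PRCR"` (responder) / `"PDSD"`.
#' @param architecture `"linear"` (default) or `"mlp"`.
#' @param split training fraction (default 0.7).
#' @param seed RNG seed (split and optimizer initialization).
#' @param hidden hidden-layer size for `"mlp"` (default 4).
#' @param min_train minimum training samples (default 10).
#' @return an `irapass_model`; metadata holds split indices, seed and (for
#'   mlp) the full \pkg{nnet} fit.
#' @export
fit_scorer <- function(features, response, architecture = c("linear", "mlp"),
                       split = 0.7, seed = 1, hidden = 4, min_train = 10) {
  architecture <- match.arg(architecture)
  features <- as.matrix(features)
  y <- as.integer(response == "PRCR")
  n <- nrow(features)
  n_train <- round(split * n)
  if (n_train < min_train) stop("fewer than ", min_train, " training samples")
  set.seed(seed)
  train <- sort(sample.int(n, n_train))
  xtr <- features[train, , drop = FALSE]
  xtr[is.na(xtr)] <- mean(xtr, na.rm = TRUE)
  ytr <- y[train]
  meta <- list(architecture = architecture, split = split, seed = seed,
               train_idx = train, test_idx = setdiff(seq_len(n), train))
  if (architecture == "linear") {
    dat <- data.frame(..y = ytr, xtr, check.names = FALSE)
    fit <- suppressWarnings(glm(..y ~ ., data = dat, family = binomial()))
    beta <- coef(fit)
    beta[is.na(beta)] <- 0
    irapass_model(colnames(features), beta[-1], intercept = beta[1],
                  metadata = meta)
  } else {
    fit <- nnet::nnet(xtr, ytr, size = hidden, skip = TRUE, decay = 1e-3,
                      entropy = TRUE, maxit = 500, trace = FALSE)
    meta$nnet_fit <- fit
    m <- linear_export(fit, colnames(features), strict = FALSE)
    m$metadata <- meta
    m
  }
}

#' Equivalent-linear export of an MLP scorer
#'
#' A skip-layer \pkg{nnet} fit decomposes into a linear part (the skip
#' weights) plus the hidden layer's contribution. When the hidden layer's
#' output weights are negligible (identity/zero-initialized hidden layer that
#' stayed inactive), the skip weights are an exact linear equivalent of the
#' network; otherwise `strict = TRUE` refuses to export.
#'
#' @param fit a [nnet::nnet()] fit with `skip = TRUE`.
#' @param feature_names feature names in input order.
#' @param strict error if the hidden layer carries non-negligible weight
#'   (default TRUE; tolerance `tol`).
#' @param tol hidden output-weight magnitude treated as negligible (1e-6).
#' @return an `irapass_model` built from the skip weights.
#' @export
linear_export <- function(fit, feature_names, strict = TRUE, tol = 1e-6) {
  if (!inherits(fit, "nnet")) stop("fit must be an nnet model")
  nin <- fit$n[1]; nhid <- fit$n[2]
  wts <- fit$wts
  # nnet weight layout: hidden units first ((nin+1)*nhid), then output unit:
  # bias, hidden->out (nhid), skip in->out (nin)
  off <- (nin + 1) * nhid
  out_w <- wts[(off + 1):length(wts)]
  bias <- out_w[1]
  hid_out <- if (nhid > 0) out_w[2:(1 + nhid)] else numeric()
  skip_w <- out_w[(2 + nhid):length(out_w)]
  if (strict && length(hid_out) && max(abs(hid_out)) > tol)
    stop("hidden layer carries non-negligible weight; no exact linear export")
  irapass_model(feature_names, skip_w, intercept = bias)
}

#' Score samples with an IRAPAss model
#'
#' The score is the dot product of the model coefficients with the sample's
#' raw PDUI feature values, plus the intercept. Every model feature must be
#' present in the input; with `impute_missing = TRUE`, absent features and
#' missing values are replaced by the per-feature mean over the supplied
#' samples (or 0.5 for a single sample vector).
#'
#' @param model an [irapass_model()].
#' @param pdui a [pdui_table()] (events x samples) or a named numeric vector
#'   of one sample's PDUI features.
#' @param impute_missing allow mean-imputation of absent features (default
#'   FALSE: error listing the missing features).
#' @return named numeric vector of per-sample scores.
#' @export
irapass_score <- function(model, pdui, impute_missing = FALSE) {
  stopifnot(inherits(model, "irapass_model"))
  if (is.null(dim(pdui))) pdui <- matrix(pdui, ncol = 1,
                                         dimnames = list(names(pdui), "sample"))
  miss <- setdiff(model$features, rownames(pdui))
  if (length(miss) && !impute_missing)
    stop("model features absent from input: ", paste(miss, collapse = ", "))
  X <- matrix(NA_real_, length(model$features), ncol(pdui),
              dimnames = list(model$features, colnames(pdui)))
  have <- intersect(model$features, rownames(pdui))
  X[have, ] <- unclass(pdui)[have, , drop = FALSE]
  if (impute_missing) {
    fill <- rowMeans(X, na.rm = TRUE)
    fill[is.nan(fill)] <- 0.5
    for (i in seq_len(nrow(X))) X[i, is.na(X[i, ])] <- fill[i]
  }
  drop(crossprod(X, model$coefficients)) + model$intercept
}

#' Evaluate an IRAPAss score against response and survival
#'
#' Computes the response ROC/AUC (responders as cases: AUC > 0.5 means
#' responders score higher), an optimal cutoff (Youden index by default,
#' median split optional), high/low score groups, Kaplan-Meier fits with the
#' log-rank p-value, and a multivariate Cox model of the score group plus any
#' supplied covariates.
#'
#' @param scores named per-sample numeric scores.
#' @param response per-sample `"PRCR"`/`"PDSD"` labels (NA allowed).
#' @param os_time,os_event optional survival outcome.
#' @param covariates optional data.frame of extra per-sample covariates for
#'   the multivariate Cox fit.
#' @param cutoff `"youden"` (default) or `"median"`.
#' @param min_events minimum deaths for survival analyses (default 10).
#' @return list of class `score_evaluation`: `auc`, `roc`, `cutoff`,
#'   `group`, `km_fit`, `logrank_p`, `cox` (term, hr, lower, upper, p).
#' @export
evaluate_scores <- function(scores, response = NULL, os_time = NULL,
                            os_event = NULL, covariates = NULL,
                            cutoff = c("youden", "median"), min_events = 10) {
  cutoff <- match.arg(cutoff)
  out <- list(auc = NA_real_, roc = NULL, cutoff = NA_real_, group = NULL,
              km_fit = NULL, logrank_p = NA_real_, cox = NULL)
  if (!is.null(response)) {
    ok <- !is.na(response) & !is.na(scores)
    if (length(unique(response[ok])) < 2) {
      warning("single response class; ROC skipped")
    } else {
      roc <- pROC::roc(response[ok], scores[ok], levels = c("PDSD", "PRCR"),
                       direction = "<", quiet = TRUE)
      out$auc <- as.numeric(pROC::auc(roc))
      out$roc <- data.frame(threshold = roc$thresholds,
                            sensitivity = roc$sensitivities,
                            specificity = roc$specificities)
      if (cutoff == "youden") {
        best <- pROC::coords(roc, "best", best.method = "youden",
                             transpose = FALSE)
        out$cutoff <- best$threshold[1]
      }
    }
  }
  if (is.na(out$cutoff) || cutoff == "median")
    out$cutoff <- median(scores, na.rm = TRUE)
  grp <- factor(ifelse(scores > out$cutoff, "high", "low"),
                levels = c("low", "high"))
  names(grp) <- names(scores)
  out$group <- grp
  if (!is.null(os_time) && !is.null(os_event) &&
      sum(os_event, na.rm = TRUE) >= min_events && nlevels(droplevels(grp)) == 2) {
    y <- survival::Surv(os_time, os_event)
    out$km_fit <- survival::survfit(y ~ grp)
    sd_ <- survival::survdiff(y ~ grp)
    out$logrank_p <- stats::pchisq(sd_$chisq, length(sd_$n) - 1,
                                   lower.tail = FALSE)
    dat <- data.frame(group = grp)
    if (!is.null(covariates)) dat <- cbind(dat, covariates)
    fit <- survival::coxph(y ~ ., data = dat)
    s <- summary(fit)
    out$cox <- data.frame(term = rownames(s$coefficients),
                          hr = s$conf.int[, "exp(coef)"],
                          lower = s$conf.int[, "lower .95"],
                          upper = s$conf.int[, "upper .95"],
                          p = s$coefficients[, "Pr(>|z|)"],
                          row.names = NULL)
  }
  class(out) <- "score_evaluation"
  out
}

#' End-to-end IRAPAss construction on a cohort pair
#'
#' Runs the full scoring-system pipeline on two cohorts sharing an event
#' universe: (1) differential APA calling per cohort (candidate events =
#' union of calls); (2) CS profiles and event-pathway GSEA separately within
#' responders and non-responders of each cohort; (3) the three-filter immune
#' screen; (4) univariate Cox then LASSO Cox survival selection on one
#' cohort; (5) scorer training on the pooled "metaAPA" samples with a 70/30
#' split.
#'
#' @param cohort1,cohort2 cohort lists as returned by [simulate_cohort()]
#'   (elements `pdui`, `expr`, `clinical`, `gene_sets`).
#' @param B permutations for the differential test (default 1000).
#' @param n_perm GSEA permutations (default 1000).
#' @param seed RNG seed for every stochastic stage.
#' @param cox_cohort which cohort drives the Cox/LASSO stage (default 1).
#' @param score_threshold,fdr_threshold immune-screen cutoffs.
#' @param architecture scorer architecture (default `"linear"`).
#' @return list: `model`, `diff` (per cohort), `screen`, `cox_table`,
#'   `lasso`, `candidate_events`, `selected_events`.
#' @export
build_irapass <- function(cohort1, cohort2, B = 1000, n_perm = 1000, seed = 1,
                          cox_cohort = 1, score_threshold = 0.995,
                          fdr_threshold = 0.05, architecture = "linear") {
  cohorts <- list(cohort1, cohort2)
  labels <- lapply(cohorts, function(co)
    setNames(co$clinical$response, co$clinical$sample_id))
  diffs <- lapply(seq_along(cohorts), function(i)
    diff_apa(cohorts[[i]]$pdui, labels[[i]], B = B, seed = seed + i))
  candidates <- unique(unlist(lapply(diffs, function(d) d$event_id[d$called])))
  if (length(candidates) < 2) stop("fewer than 2 candidate differential events")
  assoc <- lapply(seq_along(cohorts), function(i) {
    co <- cohorts[[i]]
    pd <- pdui_table(unclass(co$pdui)[candidates, , drop = FALSE])
    grp_samples <- split(co$clinical$sample_id, co$clinical$response)
    lapply(list(responder = grp_samples$PRCR, nonresponder = grp_samples$PDSD),
           function(ss) {
             cs <- suppressMessages(correlation_score(co$expr, pd, samples = ss))
             event_pathway_associations(cs, co$gene_sets, n_perm = n_perm,
                                        seed = seed + i)
           })
  })
  screen <- screen_immune_events(assoc, score_threshold, fdr_threshold)
  if (!length(screen$events)) stop("no events survive the immune screen")
  cc <- cohorts[[cox_cohort]]
  feat_cox <- t(unclass(cc$pdui)[screen$events, cc$clinical$sample_id, drop = FALSE])
  cox_tab <- univariate_cox(feat_cox, cc$clinical$os_time, cc$clinical$os_event)
  passing <- cox_tab$feature[cox_tab$passed]
  lasso <- NULL
  selected <- passing
  if (length(passing) >= 2) {
    lasso <- lasso_cox(feat_cox[, passing, drop = FALSE],
                       cc$clinical$os_time, cc$clinical$os_event, seed = seed)
    if (length(lasso$selected)) selected <- lasso$selected
  }
  if (!length(selected)) selected <- screen$events
  m1 <- unclass(cohorts[[1]]$pdui)[selected, , drop = FALSE]
  m2 <- unclass(cohorts[[2]]$pdui)[selected, , drop = FALSE]
  colnames(m1) <- paste0("c1_", colnames(m1))
  colnames(m2) <- paste0("c2_", colnames(m2))
  meta_pdui <- cbind(m1, m2)
  meta_resp <- c(setNames(labels[[1]], paste0("c1_", names(labels[[1]]))),
                 setNames(labels[[2]], paste0("c2_", names(labels[[2]]))))
  model <- fit_scorer(t(meta_pdui), meta_resp[colnames(meta_pdui)],
                      architecture = architecture, seed = seed)
  model$metadata$meta_pdui <- meta_pdui
  model$metadata$meta_response <- meta_resp[colnames(meta_pdui)]
  list(model = model, diff = diffs, screen = screen, cox_table = cox_tab,
       lasso = lasso, candidate_events = candidates,
       selected_events = selected)
}
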