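#' Group-mean PDUI per event
#'
#' Averages PDUI over the non-missing samples of each group. Events with
#' fewer than `min_per_group` non-missing values in any group are flagged
#' (`usable = FALSE`) and excluded from downstream calling.
#'
#' @param pdui a [pdui_table()] (events x samples).
#' @param labels per-sample group labels, named by sample id or aligned with
#'   `colnames(pdui)`.
#' @param min_per_group minimum non-missing samples per group (default 3).
#' @return list with `means` (events x groups matrix), `n_used` (non-missing
#'   counts), `usable` (logical per event), `groups` (level order).
#' @export
group_mean_pdui <- function(pdui, labels, min_per_group = 3) {
  labels <- resolve_labels(pdui, labels)
  groups <- unique(labels[!is.na(labels)])
  if (length(groups) < 1) stop("no non-missing group labels")
  for (g in groups) if (sum(labels == g, na.rm = TRUE) == 0)
    stop("group with zero samples: ", g)
  V <- unclass(pdui); V[is.na(V)] <- 0
  U <- !is.na(unclass(pdui))
  ind <- vapply(groups, function(g) as.numeric(!is.na(labels) & labels == g),
                numeric(length(labels)))
  n_used <- U %*% ind
  sums <- V %*% ind
  means <- sums / n_used
  means[n_used == 0] <- NA_real_
  colnames(means) <- colnames(n_used) <- groups
  usable <- apply(n_used >= min_per_group, 1, all)
  structure(list(means = means, n_used = n_used, usable = usable,
                 groups = groups), class = "group_means")
}

resolve_labels <- function(pdui, labels) {
  if (!is.null(names(labels))) {
    miss <- setdiff(colnames(pdui), names(labels))
    if (length(miss)) stop("labels missing for samples: ", paste(head(miss, 3), collapse = ", "))
    labels <- labels[colnames(pdui)]
  } else if (length(labels) != ncol(pdui)) {
    stop("labels must be named by sample or have length ncol(pdui)")
  }
  as.character(labels)
}

#' Difference of group-mean PDUI
#'
#' `delta_pdui = Mean_PDUI_GroupA - Mean_PDUI_GroupB`; positive values mean
#' higher distal usage (longer 3'-UTR) in group A.
#'
#' @param means a `group_means` object from [group_mean_pdui()].
#' @param group_a,group_b group labels present in `means`.
#' @return named numeric vector of per-event deltas (NA if either mean is
#'   missing).
#' @export
delta_pdui <- function(means, group_a, group_b) {
  for (g in c(group_a, group_b)) if (!g %in% means$groups)
    stop("unknown group label: ", g)
  means$means[, group_a] - means$means[, group_b]
}

#' Permutation p-values for differential PDUI
#'
#' Two-sided label-permutation test on the between-group mean-PDUI difference.
#' Labels are permuted jointly across all events, preserving between-event
#' correlation. With `method = "sample"` the empirical p uses the add-one
#' estimator `p = (1 + #\{|delta_perm| >= |delta_obs|\}) / (B + 1)`, so p > 0
#' always. With `method = "exhaustive"` all distinct assignments of the
#' group-A label set are enumerated (feasible only for small cohorts) and
#' `p = #\{|delta| >= |delta_obs|\} / n_assignments` (the observed assignment
#' is among them).
#'
#' Events flagged unusable by [group_mean_pdui()] get NA.
#'
#' @param pdui a [pdui_table()].
#' @param labels two-group labels (see [group_mean_pdui()]).
#' @param B number of random permutations (default 1000; < 100 warns).
#' @param seed integer RNG seed.
#' @param method `"sample"` (Monte-Carlo) or `"exhaustive"`.
#' @param min_per_group passed to [group_mean_pdui()].
#' @return list with `p` (named per-event), `delta` (observed), `means`.
#' @export
permutation_pvalues <- function(pdui, labels, B = 1000, seed = 1,
                                method = c("sample", "exhaustive"),
                                min_per_group = 3) {
  method <- match.arg(method)
  labels <- resolve_labels(pdui, labels)
  groups <- unique(labels[!is.na(labels)])
  if (length(groups) != 2) stop("permutation test requires exactly two groups")
  if (any(table(labels) < 2)) stop("each group needs >= 2 samples")
  if (method == "sample") {
    if (B < 1) stop("B must be >= 1")
    if (B < 100) warning("B < 100 gives a coarse permutation p-value")
  }
  gm <- group_mean_pdui(pdui, labels, min_per_group = min_per_group)
  d_obs <- delta_pdui(gm, groups[1], groups[2])
  use <- which(!is.na(labels))
  lab <- labels[use]
  M <- unclass(pdui)[, use, drop = FALSE]
  V <- M; V[is.na(V)] <- 0
  U <- (!is.na(M)) * 1
  s_tot <- rowSums(V); c_tot <- rowSums(U)
  n <- length(lab); n_a <- sum(lab == groups[1])
  if (method == "exhaustive") {
    idx <- utils::combn(n, n_a)
    IA <- matrix(0, n, ncol(idx))
    IA[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n_a))] <- 1
  } else {
    set.seed(seed)
    IA <- vapply(seq_len(B), function(b) {
      z <- numeric(n); z[sample.int(n, n_a)] <- 1; z
    }, numeric(n))
  }
  sA <- V %*% IA; cA <- U %*% IA
  mA <- sA / cA; mA[cA == 0] <- NA
  cB <- c_tot - cA
  mB <- (s_tot - sA) / cB; mB[cB == 0] <- NA
  d_perm <- abs(mA - mB)
  hits <- rowSums(d_perm >= abs(d_obs), na.rm = TRUE)
  p <- if (method == "exhaustive") hits / ncol(IA) else (1 + hits) / (ncol(IA) + 1)
  p[is.na(d_obs) | !gm$usable] <- NA_real_
  names(p) <- rownames(pdui)
  list(p = p, delta = d_obs, means = gm,
       group_a = groups[1], group_b = groups[2])
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up adjustment via [stats::p.adjust()] with input validation
#' (p must lie in (0, 1]); NA propagated.
#'
#' @param p numeric vector of raw p-values.
#' @return vector of BH q-values, order-preserving with the input.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential APA events
#'
#' An event is called iff `|delta_pdui| >= delta_threshold` (inclusive) and
#' `p < p_threshold` (exclusive). With group A = responders and group B =
#' non-responders, `delta > 0` (lower distal usage in non-responders) is
#' labelled `"shortened"` and `delta < 0` `"lengthened"`, both referring to
#' the 3'-UTR in group B relative to group A; uncalled events get `"none"`.
#'
#' @param delta per-event delta-PDUI (group A minus group B).
#' @param p per-event p-values (raw permutation p by default; pass q-values
#'   to screen on FDR instead).
#' @param delta_threshold effect-size cutoff (default 0.1, inclusive).
#' @param p_threshold significance cutoff (default 0.05, exclusive).
#' @param n_used optional per-group non-missing counts to carry through.
#' @return `diff_apa_result` data.frame: event_id, delta_pdui, perm_p, fdr_q,
#'   direction, called.
#' @export
call_differential <- function(delta, p, delta_threshold = 0.1,
                              p_threshold = 0.05, n_used = NULL) {
  if (length(delta) != length(p)) stop("delta and p lengths differ")
  q <- bh_fdr(p)
  called <- !is.na(delta) & !is.na(p) &
    abs(delta) >= delta_threshold & p < p_threshold
  direction <- ifelse(!called, "none", ifelse(delta > 0, "shortened", "lengthened"))
  res <- data.frame(
    event_id = if (!is.null(names(delta))) names(delta) else seq_along(delta),
    delta_pdui = as.numeric(delta), perm_p = as.numeric(p), fdr_q = q,
    direction = direction, called = called,
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(n_used)) res <- cbind(res, n_used)
  attr(res, "delta_threshold") <- delta_threshold
  attr(res, "p_threshold") <- p_threshold
  class(res) <- c("diff_apa_result", "data.frame")
  res
}

#' Two-group differential APA pipeline
#'
#' Convenience wrapper: permutation test + BH-FDR + calling rule.
#'
#' @inheritParams permutation_pvalues
#' @inheritParams call_differential
#' @param use_fdr if TRUE, the significance criterion screens on BH q instead
#'   of raw permutation p (default FALSE: raw p < 0.05).
#' @return a `diff_apa_result` data.frame (see [call_differential()]).
#' @export
diff_apa <- function(pdui, labels, B = 1000, seed = 1, delta_threshold = 0.1,
                     p_threshold = 0.05, use_fdr = FALSE, min_per_group = 3,
                     method = "sample") {
  pt <- permutation_pvalues(pdui, labels, B = B, seed = seed, method = method,
                            min_per_group = min_per_group)
  p_for_call <- if (use_fdr) bh_fdr(pt$p) else pt$p
  res <- call_differential(pt$delta, pt$p, delta_threshold, p_threshold)
  if (use_fdr) {
    res$called <- !is.na(res$delta_pdui) & !is.na(res$fdr_q) &
      abs(res$delta_pdui) >= delta_threshold & res$fdr_q < p_threshold
    res$direction <- ifelse(!res$called, "none",
                            ifelse(res$delta_pdui > 0, "shortened", "lengthened"))
  }
  attr(res, "group_a") <- pt$group_a
  attr(res, "group_b") <- pt$group_b
  res
}

#' One-vs-rest differential APA over three subgroups
#'
#' Runs the two-group machinery once per focal subgroup against the pooled
#' remainder (TN vs TA+TS, TA vs TN+TS, TS vs TN+TA).
#'
#' @inheritParams diff_apa
#' @param subgroups per-sample labels in `{TN, TA, TS}` (or any >= 2 levels).
#' @return named list of `diff_apa_result`, keyed by focal subgroup.
#' @export
one_vs_rest_differential <- function(pdui, subgroups, B = 1000, seed = 1, ...) {
  subgroups <- resolve_labels(pdui, subgroups)
  lev <- sort(unique(subgroups[!is.na(subgroups)]))
  expected <- c("TA", "TS", "TN")
  if (all(lev %in% expected)) {
    miss <- setdiff(expected, lev)
    if (length(miss)) stop("missing subgroup: ", paste(miss, collapse = ", "))
    lev <- expected
  }
  out <- lapply(lev, function(g) {
    lab <- ifelse(is.na(subgroups), NA, ifelse(subgroups == g, g, "rest"))
    diff_apa(pdui, lab, B = B, seed = seed, ...)
  })
  names(out) <- lev
  out
}

#' Gradient (monotone) PDUI events across ordered subgroups
#'
#' Reports events whose group-mean PDUI is strictly monotone across the
#' stated subgroup order and whose range (max - min) reaches
#' `delta_threshold`.
#'
#' @param means a `group_means` object over exactly the ordered groups, or an
#'   events x 3 matrix of means.
#' @param order character vector giving the subgroup order (default
#'   `c("TA","TS","TN")`).
#' @param delta_threshold minimum max-min mean difference (default 0.1).
#' @return data.frame event_id, direction (`increasing`/`decreasing`), range.
#' @export
gradient_events <- function(means, order = c("TA", "TS", "TN"),
                            delta_threshold = 0.1) {
  m <- if (inherits(means, "group_means")) means$means else as.matrix(means)
  if (!all(order %in% colnames(m))) stop("means lack the ordered groups")
  m <- m[, order, drop = FALSE]
  ok <- stats::complete.cases(m)
  d1 <- m[, 2] - m[, 1]; d2 <- m[, 3] - m[, 2]
  inc <- ok & d1 > 0 & d2 > 0
  dec <- ok & d1 < 0 & d2 < 0
  rng <- apply(m, 1, function(x) diff(range(x)))
  keep <- (inc | dec) & rng >= delta_threshold
  data.frame(event_id = rownames(m)[keep],
             direction = ifelse(inc[keep], "increasing", "decreasing"),
             range = rng[keep], stringsAsFactors = FALSE, row.names = NULL)
}

#' Default T-cell population -> class map
#'
#' Eight T-cell subpopulations mapped to the activation / suppression /
#' naive classes that define the TA / TS / TN patient subgroups.
#' @return named character vector population -> class.
#' @export
tcell_population_classes <- function() {
  c(CD8_effector = "activation", CD4_Th1 = "activation",
    T_cytotoxic = "activation", Treg = "suppression",
    T_exhausted = "suppression", T_dysfunctional = "suppression",
    CD4_naive = "naive", CD8_naive = "naive")
}

#' Assign per-sample T-cell subgroups
#'
#' Each sample is labelled by the class (activation -> TA, suppression -> TS,
#' naive -> TN) with the largest summed population fraction; exact ties are
#' broken by the fixed priority TA > TS > TN.
#'
#' @param proportions samples x populations matrix, rows summing to 1.
#' @param population_classes named map population -> class in
#'   `{activation, suppression, naive}` (default
#'   [tcell_population_classes()]).
#' @param tol row-sum tolerance (default 1e-6).
#' @return named character vector of labels in `{TA, TS, TN}`.
#' @export
assign_tcell_subgroup <- function(proportions,
                                  population_classes = tcell_population_classes(),
                                  tol = 1e-6) {
  proportions <- as.matrix(proportions)
  miss <- setdiff(colnames(proportions), names(population_classes))
  if (length(miss)) stop("population(s) missing from class map: ",
                         paste(miss, collapse = ", "))
  if (any(abs(rowSums(proportions) - 1) > tol))
    stop("sample proportions must sum to 1")
  cls <- population_classes[colnames(proportions)]
  class_levels <- c(activation = "TA", suppression = "TS", naive = "TN")
  sums <- vapply(names(class_levels), function(k)
    rowSums(proportions[, cls == k, drop = FALSE]), numeric(nrow(proportions)))
  # column order activation, suppression, naive == priority TA > TS > TN:
  # max.col(ties.method = "first") implements the tie rule.
  lab <- class_levels[max.col(sums, ties.method = "first")]
  names(lab) <- rownames(proportions)
  lab
}
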