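#' Synthetic-cohort simulation configuration
#'
#' Defines the statistical structure of a simulated immunotherapy cohort:
#' planted differential PDUI events, APA-factor regulation of event PDUI,
#' immune-pathway coupling with opposite orientation in responders versus
#' non-responders, and survival driven by a latent per-sample score.
#' Group-size defaults (23 responders / 82 non-responders) mirror the larger
#' of the two melanoma anti-PD-1 cohorts the pipeline is designed around.
#'
#' @param n_responders,n_nonresponders cohort group sizes (defaults 23 / 82).
#' @param n_events number of APA events (default 2000).
#' @param n_diff_events planted differential events (default 50).
#' @param delta_effect mean PDUI shift of planted events, in (0,1]
#'   (default 0.2; shift applied to the non-responder group mean, sign per
#'   event: negative = 3'-UTR shortening in non-responders).
#' @param n_genes expression genes (default 3000), of which the first
#'   `n_factors` are APA-factor genes.
#' @param n_factors APA factors (default 98).
#' @param n_regulated_per_factor events regulated per factor (default 20).
#' @param regulation_strength target Spearman correlation between a factor's
#'   expression and its regulated events' PDUI, in (0,1) (default 0.6).
#' @param hub_extra_targets extra planted differential events targeted by the
#'   designated hub factor (default 30), making it the ground-truth master
#'   regulator.
#' @param n_pathways number of gene sets (default 25).
#' @param pathway_size length-2 range of set sizes (default c(10, 60)).
#' @param n_immune_events planted immune-coupled events (default 20; a subset
#'   of the planted differential events).
#' @param n_immune_pathways immune pathways carrying the coupling (default 5).
#' @param immune_coupling log2-expression shift per standardized PDUI unit
#'   for coupled pathway genes (default 1.2; opposite sign in the two
#'   response groups).
#' @param concentration Beta concentration (alpha+beta) of PDUI draws
#'   (default 20, within-group spread ~0.1).
#' @param survival_baseline_hazard exponential baseline hazard per day
#'   (default 1/1000).
#' @param survival_beta effect of the latent score on the log hazard
#'   (default -1: higher latent score is protective).
#' @param latent_gap latent-score mean difference responders minus
#'   non-responders (default 1).
#' @param latent_sd latent-score noise SD (default 0.5).
#' @param censor_rate probability a sample is censored (default 0.3).
#' @param missing_rate PDUI missing-completely-at-random rate (default 0.05).
#' @param seed integer noise seed.
#' @param structure_seed seed for the planted structure (which events,
#'   factors, pathways are planted); defaults to `seed`. Two cohorts built
#'   with the same `structure_seed` and different `seed`s share their planted
#'   ground truth, emulating replicate cohorts.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_responders = 23, n_nonresponders = 82,
                              n_events = 2000, n_diff_events = 50,
                              delta_effect = 0.2,
                              n_genes = 3000, n_factors = 98,
                              n_regulated_per_factor = 20,
                              regulation_strength = 0.6,
                              hub_extra_targets = 30,
                              n_pathways = 25, pathway_size = c(10, 60),
                              n_immune_events = 20, n_immune_pathways = 5,
                              immune_coupling = 1.2,
                              concentration = 20,
                              survival_baseline_hazard = 1 / 1000,
                              survival_beta = -1,
                              latent_gap = 1, latent_sd = 0.5,
                              censor_rate = 0.3, missing_rate = 0.05,
                              seed = 1, structure_seed = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$structure_seed)) cfg$structure_seed <- seed
  stopifnot(n_responders >= 1, n_nonresponders >= 1, n_events >= 1,
            n_genes > n_factors, n_factors >= 1, n_pathways >= 1,
            length(pathway_size) == 2, pathway_size[1] >= 2)
  if (n_diff_events > n_events) stop("n_diff_events must be <= n_events")
  if (n_immune_events > n_diff_events) stop("n_immune_events must be <= n_diff_events")
  if (delta_effect <= 0 || delta_effect > 1) stop("delta_effect must be in (0,1]")
  if (regulation_strength <= 0 || regulation_strength >= 1)
    stop("regulation_strength must be in (0,1)")
  for (r in c("censor_rate", "missing_rate"))
    if (cfg[[r]] < 0 || cfg[[r]] >= 1) stop(r, " must be in [0,1)")
  if (n_events > n_genes - n_factors)
    stop("need n_events <= n_genes - n_factors (one parental gene per event)")
  class(cfg) <- "simulation_config"
  cfg
}

# sub-seed streams: one per generated table, so adding an output never
# perturbs earlier draws
sub_seed <- function(seed, k)
  as.integer((as.numeric(seed) * 17 + as.numeric(k) * 1000003) %% 2147483629)

# Spearman target -> Pearson rho of the Gaussian copula
copula_rho <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Simulate a full synthetic cohort with planted ground truth
#'
#' Emits the six pipeline inputs (PDUI, expression, clinical, gene sets,
#' interactions) plus the `synthetic_truth` record of everything planted.
#' See [simulation_config()] for the generative model. PDUI values are Beta
#' draws with per-sample mean structure; factor regulation is planted through
#' a Gaussian copula on the factor's expression; immune coupling shifts
#' pathway-gene log-expression by the event's standardized PDUI with opposite
#' sign in responders and non-responders; survival times are exponential with
#' log-hazard `survival_beta * latent_score`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `pdui`, `expr`, `clinical`, `gene_sets`,
#'   `interactions`, `truth`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  st <- cohort_structure(config)
  n <- config$n_responders + config$n_nonresponders
  samples <- sprintf("S%03d", seq_len(n))
  responder <- c(rep(TRUE, config$n_responders), rep(FALSE, config$n_nonresponders))

  # --- clinical / latent -----------------------------------------------
  set.seed(sub_seed(config$seed, 1L))
  latent <- config$latent_gap * responder + rnorm(n, 0, config$latent_sd)
  names(latent) <- samples
  rate <- config$survival_baseline_hazard * exp(config$survival_beta * latent)
  t_event <- rexp(n, rate)
  censored <- runif(n) < config$censor_rate
  os_time <- ifelse(censored, pmax(runif(n) * t_event, 0.01), t_event)
  clinical <- clinical_table(data.frame(
    sample_id = samples,
    response = ifelse(responder, "PRCR", "PDSD"),
    os_time = os_time, os_event = !censored,
    stringsAsFactors = FALSE))

  # --- factor expression latents + event PDUI --------------------------
  set.seed(sub_seed(config$seed, 2L))
  zf <- matrix(rnorm(config$n_factors * n), config$n_factors, n,
               dimnames = list(st$factors, samples))
  r <- copula_rho(config$regulation_strength)
  eps <- matrix(rnorm(config$n_events * n), config$n_events, n)
  ze <- eps
  reg <- st$factor_targets
  if (nrow(reg)) {
    fi <- match(reg$factor, st$factors)
    ei <- match(reg$event_id, st$event_ids)
    ze[ei, ] <- reg$sign * r * zf[fi, , drop = FALSE] +
      sqrt(1 - r^2) * eps[ei, , drop = FALSE]
  }
  # per-sample Beta mean: baseline plus the planted non-responder shift
  m <- matrix(st$base_mean, config$n_events, n)
  if (nrow(st$planted)) {
    pi_ <- match(st$planted$event_id, st$event_ids)
    shift <- outer(-st$planted$true_delta, as.numeric(!responder))
    m[pi_, ] <- m[pi_, ] + shift
  }
  m <- pmin(pmax(m, 0.03), 0.97)
  a <- m * config$concentration
  b <- (1 - m) * config$concentration
  pdui_vals <- qbeta(pnorm(ze), a, b)
  dimnames(pdui_vals) <- list(st$event_ids, samples)

  # --- expression ------------------------------------------------------
  set.seed(sub_seed(config$seed, 3L))
  log_expr <- matrix(st$gene_mu, config$n_genes, n) +
    matrix(rnorm(config$n_genes * n), config$n_genes, n)
  dimnames(log_expr) <- list(st$genes, samples)
  log_expr[st$factors, ] <- st$gene_mu[seq_len(config$n_factors)] + zf
  # immune coupling: pathway genes follow the event's standardized PDUI,
  # positively in responders, negatively in non-responders (or vice versa)
  if (nrow(st$immune)) {
    for (k in seq_len(nrow(st$immune))) {
      ev <- st$immune$event_id[k]
      genes_h <- intersect(st$immune_gene_map[[ev]], st$genes)
      for (grp in list(responder, !responder)) {
        v <- pdui_vals[ev, grp]
        if (sd(v) == 0) next
        z <- (v - mean(v)) / sd(v)
        sgn <- if (identical(grp, responder)) st$immune$orientation[k] else -st$immune$orientation[k]
        log_expr[genes_h, grp] <- log_expr[genes_h, grp] +
          config$immune_coupling * sgn * matrix(z, length(genes_h), sum(grp), byrow = TRUE)
      }
    }
  }
  expr <- expression_table(2^log_expr)

  # --- missingness -----------------------------------------------------
  set.seed(sub_seed(config$seed, 4L))
  if (config$missing_rate > 0) {
    mask <- matrix(runif(length(pdui_vals)) < config$missing_rate,
                   nrow(pdui_vals), ncol(pdui_vals))
    pdui_vals[mask] <- NA_real_
  }
  pdui <- pdui_table(pdui_vals)

  truth <- structure(list(
    planted_diff_events = st$planted,
    factor_targets = st$factor_targets,
    hub_factor = st$hub_factor,
    immune_events = st$immune,
    immune_gene_map = st$immune_gene_map,
    immune_pathways = st$immune_pathways,
    factors = st$factors,
    latent_score = latent,
    config = config), class = "synthetic_truth")

  list(pdui = pdui, expr = expr, clinical = clinical,
       gene_sets = st$gene_sets, interactions = st$interactions, truth = truth)
}

# planted structure shared by replicate cohorts (driven by structure_seed)
cohort_structure <- function(config) {
  set.seed(sub_seed(config$structure_seed, 0L))
  factors <- sprintf("FCT%03d", seq_len(config$n_factors))
  others <- sprintf("G%05d", seq_len(config$n_genes - config$n_factors))
  genes <- c(factors, others)
  gene_mu <- runif(config$n_genes, 1, 8)

  parents <- sample(others, config$n_events)
  event_ids <- event_id(parents, sample(paste0("chr", 1:22), config$n_events, TRUE),
                        sample.int(2e8, config$n_events))

  planted_idx <- sort(sample.int(config$n_events, config$n_diff_events))
  sign_p <- sample(c(-1, 1), config$n_diff_events, TRUE)
  # true_delta = responder mean - non-responder mean; positive = shortening
  # in non-responders
  planted <- data.frame(event_id = event_ids[planted_idx],
                        true_delta = sign_p * config$delta_effect,
                        stringsAsFactors = FALSE)

  immune_ids <- if (config$n_immune_events > 0)
    sample(planted$event_id, config$n_immune_events) else character()

  sizes <- sample(seq(config$pathway_size[1], config$pathway_size[2]),
                  config$n_pathways, TRUE)
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- sprintf("PATHWAY_%02d", seq_len(config$n_pathways))
  immune_pathways <- names(sets)[seq_len(min(config$n_immune_pathways,
                                             config$n_pathways))]
  immune <- data.frame(event_id = immune_ids,
                       pathway = rep(immune_pathways, length.out = length(immune_ids)),
                       orientation = sample(c(-1, 1), length(immune_ids), TRUE),
                       stringsAsFactors = FALSE)
  # each immune event drives its own disjoint block of its pathway's genes
  # (avoids making all set genes copies of one latent mixture)
  immune_gene_map <- list()
  for (pw in unique(immune$pathway)) {
    evs <- immune$event_id[immune$pathway == pw]
    blocks <- split(sets[[pw]], rep(seq_along(evs), length.out = length(sets[[pw]])))
    for (j in seq_along(evs)) immune_gene_map[[evs[j]]] <- blocks[[j]]
  }

  # factor -> event regulation; hub factor additionally targets planted
  # (non-immune) differential events, making it the master regulator
  hub <- factors[1]
  non_immune_diff <- setdiff(planted$event_id, immune_ids)
  hub_diff <- head(non_immune_diff, config$hub_extra_targets)
  pool <- setdiff(event_ids, c(immune_ids, hub_diff))
  pool <- sample(pool)
  hub_targets <- c(hub_diff, head(pool, config$n_regulated_per_factor))
  pool <- pool[-seq_len(min(config$n_regulated_per_factor, length(pool)))]
  ft <- list(data.frame(factor = hub, event_id = hub_targets,
                        stringsAsFactors = FALSE))
  for (f in factors[-1]) {
    if (!length(pool)) break
    take <- head(pool, config$n_regulated_per_factor)
    pool <- pool[-seq_along(take)]
    ft[[length(ft) + 1L]] <- data.frame(factor = f, event_id = take,
                                        stringsAsFactors = FALSE)
  }
  factor_targets <- do.call(rbind, ft)
  factor_targets$sign <- sample(c(-1, 1), nrow(factor_targets), TRUE)

  # synthetic protein-interaction background over the gene universe
  n_edges <- min(6000L, config$n_genes * 2L)
  ia <- sample(genes, n_edges, TRUE)
  ib <- sample(genes, n_edges, TRUE)
  hub_nb <- sample(setdiff(genes, hub), 30)
  edges <- data.frame(gene_a = c(ia, rep(hub, 30)),
                      gene_b = c(ib, hub_nb),
                      combined_score = sample(701:999, n_edges + 30, TRUE),
                      stringsAsFactors = FALSE)
  interactions <- interaction_table(edges)

  list(factors = factors, genes = genes, gene_mu = gene_mu,
       event_ids = event_ids, base_mean = runif(config$n_events, 0.25, 0.75),
       planted = planted, immune = immune, immune_gene_map = immune_gene_map,
       immune_pathways = immune_pathways,
       sets = sets, gene_sets = gene_set_collection(sets, "synthetic"),
       factor_targets = factor_targets, hub_factor = hub,
       interactions = interactions)
}

#' Simulate a pair of replicate cohorts sharing planted truth
#'
#' Builds a discovery/validation cohort pair from one planted structure
#' (same differential events, immune couplings and factor targets) with
#' independent noise, emulating the two-melanoma-cohort design. The second
#' cohort's group sizes default to 14 responders / 13 non-responders.
#'
#' @param config a [simulation_config()] for cohort 1.
#' @param n_responders2,n_nonresponders2 group sizes of cohort 2.
#' @param seed2 noise seed for cohort 2 (default `config$seed + 5000`).
#' @return list with `cohort1`, `cohort2` (each as [simulate_cohort()]).
#' @export
simulate_cohort_pair <- function(config = simulation_config(),
                                 n_responders2 = 14, n_nonresponders2 = 13,
                                 seed2 = config$seed + 5000) {
  cfg2 <- config
  cfg2$n_responders <- n_responders2
  cfg2$n_nonresponders <- n_nonresponders2
  cfg2$seed <- seed2
  list(cohort1 = simulate_cohort(config), cohort2 = simulate_cohort(cfg2))
}

#' Simulate T-cell subpopulation proportion tables
#'
#' Each sample is drawn from one of three archetypes (TA activation-dominant,
#' TS suppression-dominant, TN naive-dominant) as a Dirichlet vector over the
#' eight populations of [tcell_population_classes()], with the archetype's
#' own-class populations given concentration `alpha_own` and the rest
#' `alpha_other`.
#'
#' @param n_samples number of samples.
#' @param subgroup_mix named fractions of the TA/TS/TN archetypes (must be
#'   non-negative and sum to 1).
#' @param alpha_own,alpha_other Dirichlet concentrations (defaults 8 and 1).
#' @param seed RNG seed.
#' @return list with `proportions` (samples x 8 matrix, rows sum to 1) and
#'   `archetype` (true labels).
#' @export
simulate_tcell_proportions <- function(n_samples,
                                       subgroup_mix = c(TA = 1/3, TS = 1/3, TN = 1/3),
                                       alpha_own = 8, alpha_other = 1,
                                       seed = 1) {
  if (any(subgroup_mix < 0)) stop("subgroup_mix must be non-negative")
  if (abs(sum(subgroup_mix) - 1) > 1e-8) stop("subgroup_mix must sum to 1")
  set.seed(seed)
  cls <- tcell_population_classes()
  class_of <- c(TA = "activation", TS = "suppression", TN = "naive")
  archetype <- sample(names(subgroup_mix), n_samples, TRUE, prob = subgroup_mix)
  prop <- t(vapply(archetype, function(a) {
    alpha <- ifelse(cls == class_of[[a]], alpha_own, alpha_other)
    g <- rgamma(length(cls), shape = alpha)
    g / sum(g)
  }, numeric(length(cls))))
  colnames(prop) <- names(cls)
  rownames(prop) <- sprintf("S%03d", seq_len(n_samples))
  names(archetype) <- rownames(prop)
  list(proportions = prop, archetype = archetype)
}
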