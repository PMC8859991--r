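# Self-contained synthetic 450K cohort generator. Emulates the statistical
# structure the downstream analyses assume: subtype-specific beta shifts on
# signature probes, beta-distributed noise, longitudinal patient pairs with
# controlled transition fractions, fragment-level replication, planted
# genomic-feature enrichment, a planted stemness gradient, a planted 7-CpG
# risk panel, and exponential survival with a group hazard ratio. Identical
# seed + config give byte-identical outputs.

#' Build a synthetic cohort configuration
#'
#' All knobs of the generator with their defaults. Beta values are drawn
#' from Beta(mu*c, (1-mu)*c) where `c = noise_concentration` and the probe
#' mean `mu` is set by the sample's subtype archetype: probes of a subtype's
#' defining signature block sit at `baseline_beta + signature_effect`, all
#' other probes at `baseline_beta` (background probes at 0.5). The
#' G-CIMP-low archetype equals the G-CIMP-high archetype with the 163
#' subtype-signature probes demethylated.
#'
#' @param n_patients_per_subtype named integer vector over the 7 subtype
#'   labels (codel, gcimp_high, gcimp_low, classic_like, mesenchymal_like,
#'   lgm6_gbm, pa_like); unnamed scalar recycles to all subtypes
#' @param n_background_probes probes with no subtype signal (mean 0.5)
#' @param signature_effect mean beta separation between archetypes on
#'   signature probes (default 0.4)
#' @param noise_concentration Beta-distribution concentration `c`
#'   (default 50; larger = tighter around the archetype mean)
#' @param baseline_beta unmethylated baseline for signature probes
#' @param fraction_change proportion of gcimp_high patients whose recurrence
#'   is drawn from the gcimp_low archetype
#' @param fraction_intermediate proportion whose recurrence is drawn from
#'   the high/low archetype-mean mixture
#' @param mixture_weight_high weight of the gcimp_high archetype in the
#'   intermediate mixture (default 0.55, which centers the planted
#'   intermediate inside the classifier's index windows; 0.5 gives the
#'   literal mean midpoint, which sits on the gcimp_high-index boundary)
#' @param fragments_per_surgery tumor fragments per surgery (>= 1)
#' @param n_hyper_probes probes hypermethylated in the gcimp_low archetype,
#'   planted truth for the hypermethylated arm of differential analyses
#' @param stemness_gradient beta shift per unit of the latent stemness
#'   factor on stemness-signature probes
#' @param survival list: `baseline_hazard`, `hazard_ratio_risk_group`
#'   (hazard multiplier for patients with a planted high->low transition),
#'   `censor_hazard` (independent exponential censoring)
#' @param enrichment list of two named probability vectors, `target` and
#'   `background`, over `cgi_open_sea`, `enhancer`, `bivalent`,
#'   `motif_AP1`, `motif_SOX`: feature probabilities for the 163
#'   transition-signature probes vs all other probes (planted truth for
#'   enrichment analyses)
#' @param plant_panel plant the 7-CpG risk panel in longitudinal cohorts
#'   (hypomethylated below the published cutoffs in the primaries of
#'   transitioning patients)
#' @param seed integer master seed; all stage substreams derive from it
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(n_patients_per_subtype = 10,
                          n_background_probes = 1000,
                          signature_effect = 0.4,
                          noise_concentration = 50,
                          baseline_beta = 0.3,
                          fraction_change = 0,
                          fraction_intermediate = 0,
                          mixture_weight_high = 0.55,
                          fragments_per_surgery = 1,
                          n_hyper_probes = 28,
                          stemness_gradient = 0.5,
                          survival = list(baseline_hazard = 0.1,
                                          hazard_ratio_risk_group = 2.19,
                                          censor_hazard = 0.04),
                          enrichment = list(
                            target = c(cgi_open_sea = 0.80, enhancer = 0.50,
                                       bivalent = 0.10, motif_AP1 = 0.30,
                                       motif_SOX = 0.20),
                            background = c(cgi_open_sea = 0.35, enhancer = 0.20,
                                           bivalent = 0.10, motif_AP1 = 0.10,
                                           motif_SOX = 0.08)),
                          plant_panel = TRUE,
                          seed = 42) {
  if (length(n_patients_per_subtype) == 1 &&
      is.null(names(n_patients_per_subtype)))
    n_patients_per_subtype <- setNames(rep(n_patients_per_subtype, 7),
                                       SUBTYPE_LEVELS)
  full <- setNames(rep(0L, 7), SUBTYPE_LEVELS)
  bad <- setdiff(names(n_patients_per_subtype), SUBTYPE_LEVELS)
  if (length(bad)) stop("unknown subtype(s): ", paste(bad, collapse = ", "))
  full[names(n_patients_per_subtype)] <- as.integer(n_patients_per_subtype)
  if (any(full < 0)) stop("patient counts must be >= 0")
  stopifnot(fraction_change >= 0, fraction_change <= 1,
            fraction_intermediate >= 0, fraction_intermediate <= 1)
  if (fraction_change + fraction_intermediate > 1)
    stop("fraction_change + fraction_intermediate must be <= 1")
  stopifnot(fragments_per_surgery >= 1, signature_effect >= 0,
            noise_concentration > 0, n_background_probes >= 0)
  cfg <- list(n_patients_per_subtype = full,
              n_background_probes = as.integer(n_background_probes),
              signature_effect = signature_effect,
              noise_concentration = noise_concentration,
              baseline_beta = baseline_beta,
              fraction_change = fraction_change,
              fraction_intermediate = fraction_intermediate,
              mixture_weight_high = mixture_weight_high,
              fragments_per_surgery = as.integer(fragments_per_surgery),
              n_hyper_probes = as.integer(n_hyper_probes),
              stemness_gradient = stemness_gradient,
              survival = survival, enrichment = enrichment,
              plant_panel = isTRUE(plant_panel),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Synthetic stemness probe weights
#'
#' Standard-normal weights over generated probe IDs; a synthetic stand-in
#' for a published stemness probe-weight model, reproducible under `seed`.
#'
#' @param n_probes number of probes (default 219)
#' @param seed integer seed
#' @return signature list with `name = "stemness_219"`, `probe_ids`,
#'   `weights`
#' @export
generate_stemness_weights <- function(n_probes = 219, seed = 1) {
  set.seed(derive_seed(seed, "stemness_weights"))
  ids <- sprintf("stem%05d", seq_len(n_probes))
  list(name = "stemness_219", probe_ids = ids,
       weights = setNames(rnorm(n_probes), ids))
}

# ---- internal probe universe -------------------------------------------

# probe table with a 'role' column driving the archetype means, plus the
# signature sets over it
build_probe_universe <- function(cfg, with_panel = FALSE) {
  stem <- generate_stemness_weights(219, seed = cfg$seed)
  macro <- sprintf("mac%05d", 1:1300)
  mut <- sprintf("mut%05d", 1:1308)
  sub163 <- sprintf("sub%05d", 1:163)
  wt <- sprintf("wtp%05d", 1:914)
  bg <- if (cfg$n_background_probes > 0)
    sprintf("bkg%05d", seq_len(cfg$n_background_probes)) else character(0)
  hyp <- if (cfg$n_hyper_probes > 0)
    sprintf("hyp%05d", seq_len(cfg$n_hyper_probes)) else character(0)
  panel <- if (with_panel) biomarker_panel()$probe_id else character(0)

  mut_block <- rep(c("mut_codel", "mut_gcimp", "mut_shared"), length.out = 1308)
  wt_block <- rep(c("wt_classic", "wt_mes", "wt_lgm6", "wt_pa"),
                  length.out = 914)
  probes <- data.frame(
    probe_id = c(macro, mut, sub163, wt, stem$probe_ids, bg, hyp, panel),
    role = c(rep("macro", 1300), mut_block, rep("sub163", 163), wt_block,
             rep("stemness", 219), rep("background", length(bg)),
             rep("hyper_low", length(hyp)), rep("panel", length(panel))),
    stringsAsFactors = FALSE)
  signatures <- list(
    macro_1300 = list(name = "macro_1300", probe_ids = macro),
    idh_mut_1308 = list(name = "idh_mut_1308", probe_ids = mut),
    idh_mut_subtype_163 = list(name = "idh_mut_subtype_163",
                               probe_ids = sub163),
    idh_wt_914 = list(name = "idh_wt_914", probe_ids = wt),
    stemness_219 = stem)
  list(probes = probes, signatures = signatures)
}

# archetype mean vector for one subtype over the probe universe;
# stemness/panel probes get placeholder means that the caller overrides
archetype_mean <- function(probes, subtype, cfg) {
  b <- cfg$baseline_beta
  e <- cfg$signature_effect
  is_mut <- subtype %in% IDH_MUT_SUBTYPES
  mu <- rep(b, nrow(probes))
  role <- probes$role
  mu[role == "macro"] <- if (is_mut) b + e else b
  mu[role == "mut_codel"] <- if (subtype == "codel") b + e else b
  mu[role == "mut_gcimp"] <-
    if (subtype %in% c("gcimp_high", "gcimp_low")) b + e else b
  mu[role == "mut_shared"] <- if (is_mut) b + e else b
  mu[role == "sub163"] <-
    if (is_mut && subtype != "gcimp_low") b + e else b
  mu[role == "wt_classic"] <- if (subtype == "classic_like") b + e else b
  mu[role == "wt_mes"] <- if (subtype == "mesenchymal_like") b + e else b
  mu[role == "wt_lgm6"] <- if (subtype == "lgm6_gbm") b + e else b
  mu[role == "wt_pa"] <- if (subtype == "pa_like") b + e else b
  mu[role == "background"] <- 0.5
  mu[role == "hyper_low"] <- if (subtype == "gcimp_low") b + e else b
  mu[role == "stemness"] <- 0.5
  mu[role == "panel"] <- 0.5
  mu
}

# stemness-probe means for a latent factor s in [0,1]
stemness_means <- function(weights, s, cfg) {
  0.5 + cfg$stemness_gradient * (s - 0.5) * sign(weights)
}

draw_betas <- function(mu, cfg) {
  mu <- pmin(pmax(mu, 0.02), 0.98)
  c_ <- cfg$noise_concentration
  x <- rbeta(length(mu), mu * c_, (1 - mu) * c_)
  pmin(pmax(x, 1e-6), 1 - 1e-6)
}

# categorical genomic annotation with planted enrichment on target probes
build_annotation <- function(probes, target_ids, cfg) {
  set.seed(derive_seed(cfg$seed, "annotation"))
  n <- nrow(probes)
  tgt <- probes$probe_id %in% target_ids
  pe <- cfg$enrichment
  p_open <- ifelse(tgt, pe$target["cgi_open_sea"], pe$background["cgi_open_sea"])
  # split the non-open-sea remainder island/shore/shelf 50/35/15
  u <- runif(n)
  cgi <- ifelse(u < p_open, "open_sea",
         ifelse(u < p_open + (1 - p_open) * 0.50, "island",
         ifelse(u < p_open + (1 - p_open) * 0.85, "shore", "shelf")))
  flag <- function(key) {
    runif(n) < ifelse(tgt, pe$target[key], pe$background[key])
  }
  data.frame(
    probe_id = probes$probe_id,
    chromosome = sample(CHROM_LEVELS[1:22], n, replace = TRUE),
    position = sample.int(2e8, n, replace = TRUE),
    cgi_relation = cgi,
    enhancer = flag("enhancer"),
    bivalent = flag("bivalent"),
    chromhmm_state = sample(c("TssA", "EnhG", "Quies", "ReprPC"), n,
                            replace = TRUE),
    motif_AP1 = flag("motif_AP1"),
    motif_SOX = flag("motif_SOX"),
    stringsAsFactors = FALSE)
}

blank_sheet_row <- function(sample_id, patient_id, timepoint, fragment,
                            grade, idh, codel) {
  data.frame(sample_id = sample_id, patient_id = patient_id,
             timepoint = timepoint, fragment_index = fragment,
             grade = grade, idh_status = idh, codel_status = codel,
             radiation = "unknown", tmz = "unknown",
             survival_time = NA_real_, survival_event = NA,
             age_years = NA_real_, sex = "unknown",
             stringsAsFactors = FALSE)
}

subtype_meta <- function(subtype) {
  if (subtype %in% IDH_MUT_SUBTYPES)
    list(idh = "mutant", codel = if (subtype == "codel") "codel" else "non_codel")
  else list(idh = "wildtype", codel = "non_codel")
}

#' Generate a single-timepoint reference cohort
#'
#' One primary sample per patient, subtype archetypes as planted truth.
#' Each sample additionally carries a latent stemness factor driving its
#' stemness-signature probes.
#'
#' @param config a [cohort_config()]
#' @return list with `beta` (matrix), `sheet`, `annotation`, `signatures`,
#'   `truth` (sample_id, patient_id, subtype, stemness) and `config`
#' @export
generate_reference_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_total <- sum(config$n_patients_per_subtype)
  if (n_total == 0) stop("configuration yields zero samples")
  uni <- build_probe_universe(config, with_panel = FALSE)
  probes <- uni$probes
  stem_w <- uni$signatures$stemness_219$weights
  stem_idx <- which(probes$role == "stemness")

  set.seed(derive_seed(config$seed, "reference"))
  subtype <- rep(names(config$n_patients_per_subtype),
                 config$n_patients_per_subtype)
  patient <- sprintf("PT%04d", seq_len(n_total))
  sample_id <- paste0(patient, "_primary_1")
  s_latent <- runif(n_total)

  beta <- matrix(NA_real_, nrow(probes), n_total,
                 dimnames = list(probes$probe_id, sample_id))
  mu_cache <- lapply(setNames(SUBTYPE_LEVELS, SUBTYPE_LEVELS),
                     function(st) archetype_mean(probes, st, config))
  for (j in seq_len(n_total)) {
    mu <- mu_cache[[subtype[j]]]
    mu[stem_idx] <- stemness_means(stem_w, s_latent[j], config)
    beta[, j] <- draw_betas(mu, config)
  }

  sheet <- do.call(rbind, lapply(seq_len(n_total), function(j) {
    m <- subtype_meta(subtype[j])
    blank_sheet_row(sample_id[j], patient[j], "primary", 1L, "unknown",
                    m$idh, m$codel)
  }))
  truth <- data.frame(sample_id = sample_id, patient_id = patient,
                      subtype = subtype, stemness = s_latent,
                      stringsAsFactors = FALSE)
  ann <- build_annotation(probes,
                          uni$signatures$idh_mut_subtype_163$probe_ids,
                          config)
  validate_beta_matrix(beta)
  list(beta = beta, sheet = sheet, annotation = ann,
       signatures = uni$signatures, truth = truth, config = config)
}

#' Generate a longitudinal cohort with planted transitions
#'
#' Every patient gets a primary and a first-recurrence surgery with
#' `fragments_per_surgery` fragments each. Among gcimp_high patients, a
#' `fraction_change` subset recurs from the gcimp_low archetype ("change"),
#' a `fraction_intermediate` subset from the high/low mixture
#' ("intermediate_change"), the rest redraw from gcimp_high ("no_change").
#' Other subtypes always recur from their own archetype. Transitioning
#' ("change") patients form the planted risk group: their survival times
#' are exponential with the baseline hazard multiplied by
#' `hazard_ratio_risk_group`, and (when `plant_panel`) their primary
#' fragments are hypomethylated below the published 7-CpG panel cutoffs.
#'
#' @param config a [cohort_config()]
#' @return list with `beta`, `sheet`, `annotation`, `signatures`, `truth`
#'   (one row per patient: subtype, category, risk_group, survival), and
#'   `planted` (dmp_hypo, dmp_hyper, enriched_features, panel probe IDs)
#' @export
generate_longitudinal_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_total <- sum(config$n_patients_per_subtype)
  if (n_total == 0) stop("configuration yields zero samples")
  if (config$fraction_change + config$fraction_intermediate > 1)
    stop("fraction_change + fraction_intermediate must be <= 1")
  uni <- build_probe_universe(config, with_panel = config$plant_panel)
  probes <- uni$probes
  stem_w <- uni$signatures$stemness_219$weights
  stem_idx <- which(probes$role == "stemness")
  panel_idx <- which(probes$role == "panel")
  panel <- biomarker_panel()

  set.seed(derive_seed(config$seed, "longitudinal"))
  subtype <- rep(names(config$n_patients_per_subtype),
                 config$n_patients_per_subtype)
  patient <- sprintf("PT%04d", seq_len(n_total))

  # transition categories among gcimp_high patients
  category <- rep("no_change", n_total)
  hi <- which(subtype == "gcimp_high")
  n_change <- round(config$fraction_change * length(hi))
  n_inter <- round(config$fraction_intermediate * length(hi))
  reassigned <- sample(hi, n_change + n_inter)
  category[reassigned[seq_len(n_change)]] <- "change"
  if (n_inter > 0)
    category[reassigned[n_change + seq_len(n_inter)]] <- "intermediate_change"

  s_primary <- runif(n_total)
  # transitioning recurrences acquire a high-stemness phenotype
  s_recur <- ifelse(category == "change", 0.5 + 0.5 * runif(n_total),
                    s_primary)

  mu_cache <- lapply(setNames(SUBTYPE_LEVELS, SUBTYPE_LEVELS),
                     function(st) archetype_mean(probes, st, config))
  w_hi <- config$mixture_weight_high
  mu_intermediate <- w_hi * mu_cache[["gcimp_high"]] +
    (1 - w_hi) * mu_cache[["gcimp_low"]]

  nf <- config$fragments_per_surgery
  n_samp <- n_total * 2 * nf
  sample_id <- character(n_samp)
  beta <- matrix(NA_real_, nrow(probes), n_samp,
                 dimnames = list(probes$probe_id, NULL))
  sheet_rows <- vector("list", n_samp)
  k <- 0
  for (j in seq_len(n_total)) {
    meta <- subtype_meta(subtype[j])
    risky <- category[j] == "change"
    for (tp in c("primary", "first_recurrence")) {
      if (tp == "primary") {
        mu <- mu_cache[[subtype[j]]]
        s <- s_primary[j]
        grade <- if (subtype[j] %in% c("gcimp_high", "gcimp_low")) "II" else "unknown"
      } else {
        mu <- switch(category[j],
                     change = mu_cache[["gcimp_low"]],
                     intermediate_change = mu_intermediate,
                     mu_cache[[subtype[j]]])
        s <- s_recur[j]
        grade <- if (risky) "IV" else "unknown"
      }
      mu[stem_idx] <- stemness_means(stem_w, s, config)
      if (length(panel_idx)) {
        # risk patients carry panel hypomethylation already at primary
        mu[panel_idx] <- if (risky) pmax(panel$cutoff - 0.10, 0.02)
                         else pmin(panel$cutoff + 0.25, 0.95)
      }
      for (f in seq_len(nf)) {
        k <- k + 1
        sid <- sprintf("%s_%s_%d", patient[j],
                       if (tp == "primary") "primary" else "rec1", f)
        sample_id[k] <- sid
        beta[, k] <- draw_betas(mu, config)
        sheet_rows[[k]] <- blank_sheet_row(sid, patient[j], tp, f, grade,
                                           meta$idh, meta$codel)
      }
    }
  }
  colnames(beta) <- sample_id
  sheet <- do.call(rbind, sheet_rows)

  # exponential survival with planted hazard ratio for the risk group
  sv <- config$survival
  set.seed(derive_seed(config$seed, "survival"))
  rate <- sv$baseline_hazard *
    ifelse(category == "change", sv$hazard_ratio_risk_group, 1)
  t_event <- rexp(n_total, rate)
  t_cens <- if (sv$censor_hazard > 0) rexp(n_total, sv$censor_hazard)
            else rep(Inf, n_total)
  surv_time <- pmin(t_event, t_cens)
  surv_event <- t_event <= t_cens
  idx <- match(sheet$patient_id, patient)
  sheet$survival_time <- surv_time[idx]
  sheet$survival_event <- surv_event[idx]

  truth <- data.frame(patient_id = patient, subtype = subtype,
                      category = category,
                      risk_group = ifelse(category == "change", "risk",
                                          "non_risk"),
                      stemness_primary = s_primary,
                      stemness_recurrence = s_recur,
                      survival_time = surv_time, survival_event = surv_event,
                      stringsAsFactors = FALSE)
  ann <- build_annotation(probes,
                          uni$signatures$idh_mut_subtype_163$probe_ids,
                          config)
  planted <- list(
    dmp_hypo = uni$signatures$idh_mut_subtype_163$probe_ids,
    dmp_hyper = probes$probe_id[probes$role == "hyper_low"],
    enriched_features = names(which(
      config$enrichment$target > config$enrichment$background)),
    panel = if (length(panel_idx)) panel$probe_id else character(0))
  validate_beta_matrix(beta)
  list(beta = beta, sheet = sheet, annotation = ann,
       signatures = uni$signatures, truth = truth, planted = planted,
       config = config)
}
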