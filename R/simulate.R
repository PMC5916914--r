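#' Configuration for a synthetic longitudinal methylome cohort
#'
#' Bundles and validates the generator's parameters. Defaults emulate a
#' two-group whole-blood cohort of 14 converters and 25 non-converters
#' sampled at baseline (M0) and follow-up (MF): per-probe baseline means
#' are drawn from a bimodal mixture (unmethylated mode near 0.1,
#' methylated mode near 0.85, as array beta distributions are), subjects
#' scatter around the probe mean with logit-scale Gaussian noise, and MF
#' adds logit-scale Gaussian drift on top of each subject's M0 value.
#' Planted signal is added on the beta scale at MF only: VMP shifts to
#' every member of a target group, epimutation offsets to single
#' (probe, subject) pairs.
#'
#' @param n_converters,n_nonconverters group sizes (defaults 14 and 25).
#' @param n_probes number of probes.
#' @param mix_weight_low probability a probe sits in the low-methylation
#'   mode (default 0.5).
#' @param mode_low,mode_high baseline means of the two modes (0.1, 0.85).
#' @param mode_sd logit-scale sd of probe baselines within a mode (0.5).
#' @param noise_sd logit-scale sd of within-group, between-subject noise
#'   (default 0.02).
#' @param drift_sd logit-scale sd of the M0->MF longitudinal drift
#'   (default 0.02).
#' @param n_vmp number of planted VMP probes (group-level MF shift).
#' @param vmp_shift beta-scale shift added at MF to every member of
#'   `vmp_group` at a planted VMP probe (default 0.15; must be >= 0.1 to
#'   be a true VMP at the conventional threshold).
#' @param vmp_group group receiving the VMP shift (default "converter").
#' @param n_epimutation number of planted private epimutations, each a
#'   distinct (probe, subject) pair on a probe carrying no other signal.
#' @param epimutation_offset beta-scale offset added at MF to the single
#'   carrier (default 0.25); sign is drawn at random per plant.
#' @param epimutation_group group the carriers are drawn from
#'   (default "converter").
#' @param detp_fail_rate,low_beadcount_rate optional QC corruption rates
#'   (fraction of cells given a failing detection p-value / a beadcount
#'   below 3); both default to 0 so statistical tests are unentangled
#'   from QC.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration including the seed.
#' @return a validated `methvar_sim_config` list.
#' @export
sim_config <- function(n_converters = 14, n_nonconverters = 25,
                       n_probes = 10000,
                       mix_weight_low = 0.5, mode_low = 0.1, mode_high = 0.85,
                       mode_sd = 0.5, noise_sd = 0.02, drift_sd = 0.02,
                       n_vmp = 0, vmp_shift = 0.15, vmp_group = "converter",
                       n_epimutation = 0, epimutation_offset = 0.25,
                       epimutation_group = "converter",
                       detp_fail_rate = 0, low_beadcount_rate = 0,
                       seed = 1L) {
  cfg <- list(n_converters = n_converters, n_nonconverters = n_nonconverters,
              n_probes = n_probes, mix_weight_low = mix_weight_low,
              mode_low = mode_low, mode_high = mode_high, mode_sd = mode_sd,
              noise_sd = noise_sd, drift_sd = drift_sd,
              n_vmp = n_vmp, vmp_shift = vmp_shift, vmp_group = vmp_group,
              n_epimutation = n_epimutation,
              epimutation_offset = epimutation_offset,
              epimutation_group = epimutation_group,
              detp_fail_rate = detp_fail_rate,
              low_beadcount_rate = low_beadcount_rate,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_converters >= 0, n_nonconverters >= 0, n_probes >= 1,
              mix_weight_low >= 0, mix_weight_low <= 1,
              mode_low > 0, mode_low < 1, mode_high > 0, mode_high < 1,
              mode_sd >= 0, noise_sd >= 0, drift_sd >= 0,
              n_vmp >= 0, n_epimutation >= 0,
              vmp_shift > 0, vmp_shift < 1,
              epimutation_offset > 0, epimutation_offset < 1,
              vmp_group %in% c("converter", "nonconverter"),
              epimutation_group %in% c("converter", "nonconverter"),
              detp_fail_rate >= 0, detp_fail_rate < 1,
              low_beadcount_rate >= 0, low_beadcount_rate < 1,
              n_vmp + n_epimutation <= n_probes)
  })
  structure(cfg, class = "methvar_sim_config")
}

#' Simulate a longitudinal two-group methylome cohort with known truth
#'
#' Generates beta matrices at both timepoints, the matching sample sheet,
#' optional QC-metric matrices, and a truth table of the planted signal.
#' Per probe j a baseline mean m_j comes from the bimodal mixture; subject
#' i's baseline beta is `plogis(qlogis(m_j) + e_ij)` with
#' `e_ij ~ N(0, noise_sd)`; the follow-up beta adds drift
#' `d_ij ~ N(0, drift_sd)` on the logit scale to the subject's own
#' baseline logit, so each subject is compared to itself. Planted VMP
#' shifts and epimutation offsets are then added on the beta scale at MF
#' only, and all betas are clipped to \[1e-6, 1 - 1e-6\]; any clipped
#' planted value is recorded in the truth table. With zero noise, zero
#' drift and no plants, M0 and MF equal the baseline matrix exactly.
#'
#' Sample ids are `<subject>_M0` / `<subject>_MF`; subjects are
#' `C01..` (converters) and `N01..` (non-converters); probes `cg000001..`.
#'
#' @param config a `methvar_sim_config` from [sim_config()].
#' @return list with `betas_m0`, `betas_mf` (probes x samples), `sheet`
#'   (sample sheet covering both timepoints), `detection_p`, `beadcount`
#'   (lists with `m0`/`mf` matrices, or `NULL` when no corruption was
#'   requested), and `truth` (list `vmp` and `epimutation` data frames).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "methvar_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  eps <- 1e-6
  n_sub <- cfg$n_converters + cfg$n_nonconverters
  subjects <- c(sprintf("C%02d", seq_len(cfg$n_converters)),
                sprintf("N%02d", seq_len(cfg$n_nonconverters)))
  groups <- c(rep("converter", cfg$n_converters),
              rep("nonconverter", cfg$n_nonconverters))
  probes <- sprintf("cg%06d", seq_len(cfg$n_probes))

  low <- runif(cfg$n_probes) < cfg$mix_weight_low
  mode_mean <- ifelse(low, cfg$mode_low, cfg$mode_high)
  m <- plogis(qlogis(mode_mean) + rnorm(cfg$n_probes, 0, cfg$mode_sd))

  gauss <- function(sd) {
    if (sd == 0) return(matrix(0, cfg$n_probes, n_sub))
    matrix(rnorm(cfg$n_probes * n_sub, 0, sd), cfg$n_probes, n_sub)
  }
  eta0 <- matrix(qlogis(m), cfg$n_probes, n_sub)
  e0 <- gauss(cfg$noise_sd)
  d <- gauss(cfg$drift_sd)
  # exact identity where the perturbation is zero
  b0 <- matrix(m, cfg$n_probes, n_sub)
  nz <- e0 != 0
  b0[nz] <- plogis(eta0[nz] + e0[nz])
  bf <- b0
  nzf <- d != 0
  bf[nzf] <- plogis(eta0[nzf] + e0[nzf] + d[nzf])

  dimnames(b0) <- list(probes, paste0(subjects, "_M0"))
  dimnames(bf) <- list(probes, paste0(subjects, "_MF"))

  # planted signal: disjoint probe sets, MF only, beta scale
  plant_probes <- sample.int(cfg$n_probes, cfg$n_vmp + cfg$n_epimutation)
  vmp_idx <- plant_probes[seq_len(cfg$n_vmp)]
  epi_idx <- plant_probes[cfg$n_vmp + seq_len(cfg$n_epimutation)]

  truth_vmp <- data.frame(probe_id = character(0), group = character(0),
                          shift = numeric(0), stringsAsFactors = FALSE)
  if (cfg$n_vmp > 0) {
    target <- which(groups == cfg$vmp_group)
    # plant toward the side with headroom so the true shift is realisable
    sign_v <- ifelse(m[vmp_idx] < 0.5, 1, -1)
    for (k in seq_len(cfg$n_vmp))
      bf[vmp_idx[k], target] <- bf[vmp_idx[k], target] + sign_v[k] * cfg$vmp_shift
    truth_vmp <- data.frame(probe_id = probes[vmp_idx], group = cfg$vmp_group,
                            shift = sign_v * cfg$vmp_shift,
                            stringsAsFactors = FALSE)
  }

  truth_epi <- data.frame(probe_id = character(0), subject_id = character(0),
                          timepoint = character(0), offset = numeric(0),
                          direction = character(0), clipped = logical(0),
                          stringsAsFactors = FALSE)
  if (cfg$n_epimutation > 0) {
    carriers_pool <- which(groups == cfg$epimutation_group)
    carrier <- sample(carriers_pool, cfg$n_epimutation, replace = TRUE)
    sign_e <- sample(c(-1, 1), cfg$n_epimutation, replace = TRUE)
    # keep the plant inside [0,1]: flip sign if the offset would clip badly
    for (k in seq_len(cfg$n_epimutation)) {
      i <- epi_idx[k]; jcol <- carrier[k]
      val <- bf[i, jcol] + sign_e[k] * cfg$epimutation_offset
      if (val < eps || val > 1 - eps) {
        sign_e[k] <- -sign_e[k]
        val <- bf[i, jcol] + sign_e[k] * cfg$epimutation_offset
      }
      bf[i, jcol] <- val
    }
    truth_epi <- data.frame(probe_id = probes[epi_idx],
                            subject_id = subjects[carrier],
                            timepoint = "MF",
                            offset = sign_e * cfg$epimutation_offset,
                            direction = ifelse(sign_e > 0, "hyper", "hypo"),
                            clipped = FALSE, stringsAsFactors = FALSE)
  }

  clipped0 <- b0 < eps | b0 > 1 - eps
  clippedf <- bf < eps | bf > 1 - eps
  b0 <- pmin(pmax(b0, eps), 1 - eps)
  bf <- pmin(pmax(bf, eps), 1 - eps)
  if (nrow(truth_vmp) > 0)
    truth_vmp$n_clipped_samples <- rowSums(
      clippedf[match(truth_vmp$probe_id, probes), , drop = FALSE])
  if (nrow(truth_epi) > 0)
    truth_epi$clipped <- clippedf[cbind(match(truth_epi$probe_id, probes),
                                        match(paste0(truth_epi$subject_id, "_MF"),
                                              colnames(bf)))]

  sheet <- data.frame(
    sample_id = c(colnames(b0), colnames(bf)),
    subject_id = rep(subjects, 2),
    group = rep(groups, 2),
    timepoint = rep(c("M0", "MF"), each = n_sub),
    stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)

  detection_p <- beadcount <- NULL
  if (cfg$detp_fail_rate > 0 || cfg$low_beadcount_rate > 0) {
    mk_detp <- function(cn) {
      p <- matrix(runif(cfg$n_probes * n_sub, 0, 0.01), cfg$n_probes, n_sub,
                  dimnames = list(probes, cn))
      if (cfg$detp_fail_rate > 0) {
        fail <- runif(length(p)) < cfg$detp_fail_rate
        p[fail] <- runif(sum(fail), 0.05, 1)
      }
      p
    }
    mk_bead <- function(cn) {
      b <- matrix(sample(8:25, cfg$n_probes * n_sub, replace = TRUE),
                  cfg$n_probes, n_sub, dimnames = list(probes, cn))
      if (cfg$low_beadcount_rate > 0) {
        lowb <- runif(length(b)) < cfg$low_beadcount_rate
        b[lowb] <- sample(0:2, sum(lowb), replace = TRUE)
      }
      b
    }
    detection_p <- list(m0 = mk_detp(colnames(b0)), mf = mk_detp(colnames(bf)))
    beadcount <- list(m0 = mk_bead(colnames(b0)), mf = mk_bead(colnames(bf)))
  }

  list(betas_m0 = b0, betas_mf = bf, sheet = sheet,
       detection_p = detection_p, beadcount = beadcount,
       truth = list(vmp = truth_vmp, epimutation = truth_epi),
       config = cfg)
}

#' Precision and recall of detections against planted truth
#'
#' Scores VMP detections by exact probe match and epimutation calls by
#' exact (probe, subject) match. With an empty prediction set and
#' non-empty truth, recall is 0 and precision is `NA` (undefined).
#'
#' @param truth truth list from [simulate_cohort()] (`$vmp`,
#'   `$epimutation`).
#' @param vmp_results optional data frame from [detect_vmps()]; rows with
#'   `is_vmp` are the predictions.
#' @param epimutation_calls optional data frame from
#'   [call_epimutations()].
#' @return list with `vmp` and `epimutation`, each
#'   `list(tp, fp, fn, precision, recall)` (NULL when the corresponding
#'   predictions were not supplied).
#' @export
evaluate_recovery <- function(truth, vmp_results = NULL,
                              epimutation_calls = NULL) {
  score <- function(pred_keys, true_keys) {
    tp <- length(intersect(pred_keys, true_keys))
    fp <- length(setdiff(pred_keys, true_keys))
    fn <- length(setdiff(true_keys, pred_keys))
    list(tp = tp, fp = fp, fn = fn,
         precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
         recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
  }
  out <- list(vmp = NULL, epimutation = NULL)
  if (!is.null(vmp_results)) {
    pred <- unique(vmp_results$probe_id[vmp_results$is_vmp])
    out$vmp <- score(pred, unique(truth$vmp$probe_id))
  }
  if (!is.null(epimutation_calls)) {
    pred <- unique(paste(epimutation_calls$probe_id,
                         epimutation_calls$subject_id, sep = "\r"))
    true <- unique(paste(truth$epimutation$probe_id,
                         truth$epimutation$subject_id, sep = "\r"))
    out$epimutation <- score(pred, true)
  }
  out
}
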