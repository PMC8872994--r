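#' Parameters of the synthetic longitudinal weight-loss cohort
#'
#' Defaults describe a 43-subject cohort (37 bariatric surgery, 6 low-calorie
#' diet) sampled at 0, 2 and 12 months, with median 12-month weight loss of
#' 63.3 kg (surgery) and 13.0 kg (diet), declining serum CRP and IL-6,
#' stable TNF-alpha, rising tissue CD8+ density and stable densities for the
#' other five immune markers. `rho_within` programs the within-subject
#' correlation of each marker (on the log scale) with weight: positive for
#' markers that fall as weight falls, negative for markers that rise.
#'
#' @param ... overrides for any default parameter (see the returned list for
#'   names).
#' @return validated parameter list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(...) {
  p <- list(
    n_subjects = 43L, n_surgery = 37L, n_diet = 6L,
    timepoints = c(0, 2, 12),
    baseline_weight_median = 140, baseline_bmi_median = 52,
    # cumulative median weight loss (kg) at each timepoint, per arm
    weight_loss = list(surgery = c(0, 15.1, 63.3), diet = c(0, 1.7, 13.0)),
    # per-timepoint medians: serum (CRP ug/ml, IL-6 pg/ml, TNF-a pg/ml)
    serum_medians = list(crp = c(5.9, 4.2, 1.7), il6 = c(4.8, 1.7, 1.2),
                         tnfa = c(29.1, 31.4, 25.2)),
    # per-timepoint medians: tissue fraction of positive cells
    density_medians = list(cd56 = c(0.0071, 0.0069, 0.0116),
                           cd68 = c(0.0019, 0.0012, 0.0008),
                           cd3 = c(0.0019, 0.0009, 0.0013),
                           cd8 = c(0.0037, 0.0038, 0.0056),
                           foxp3 = c(0.00069, 0.00069, 0.00066),
                           pd1 = c(0.0011, 0.0008, 0.0012)),
    # within-subject correlation of each marker with weight
    rho_within = c(crp = 0.570, il6 = 0.459, tnfa = 0,
                   cd8 = -0.323, cd68 = 0, cd3 = 0, foxp3 = 0, cd56 = 0,
                   pd1 = 0),
    noise_cv = 0.3,
    sigma_subject_serum = 0.5,   # between-subject log-sd, serum markers
    sigma_subject_tissue = 1.0,  # between-subject log-sd, tissue densities
    sigma_loss_re = 0.25,        # log-sd of the subject loss multiplier
    sigma_weight_base = 0.12,    # log-sd of baseline weight
    sigma_bmi_base = 0.08,
    seed = 1L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) {
    stop("unknown parameters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(ov$rho_within)) {  # per-marker override, others keep defaults
    rho <- p$rho_within
    rho[names(ov$rho_within)] <- ov$rho_within
    ov$rho_within <- rho
  }
  p[names(ov)] <- ov
  with(p, {
    if (n_surgery + n_diet != n_subjects) {
      stop("n_surgery + n_diet must equal n_subjects", call. = FALSE)
    }
    if (baseline_weight_median <= 0 || baseline_bmi_median <= 0) {
      stop("baseline medians must be positive", call. = FALSE)
    }
    meds <- unlist(c(serum_medians, density_medians))
    if (any(meds <= 0)) stop("all marker medians must be positive",
                             call. = FALSE)
    if (any(abs(rho_within) > 1)) stop("|rho_within| must be <= 1",
                                       call. = FALSE)
    nt <- length(timepoints)
    lens <- c(vapply(serum_medians, length, integer(1)),
              vapply(density_medians, length, integer(1)),
              vapply(weight_loss, length, integer(1)))
    if (any(lens != nt)) {
      stop("per-timepoint medians must have one value per timepoint",
           call. = FALSE)
    }
  })
  class(p) <- "cohort_sim_params"
  p
}

# Solve the deviation-loading g such that the expected within-subject
# correlation of T + g*dev + s*eta with the standardized centered weight z
# equals rho. Moments are empirical: C = E[T z], V_T = E[T^2],
# Vdev = E[dev^2] (dev orthogonal to T and to the timepoint means of z),
# K = expected variance of within-centered noise.
.solve_dev_loading <- function(rho, C, V_T, Vdev, K) {
  corr_of <- function(g, K) (C + g * Vdev) /
    sqrt(V_T + g^2 * Vdev + K + 2 * 0)  # cov(T, dev) = 0 by construction
  if (abs(rho) < 1e-12) {
    g <- if (Vdev > 1e-12) -C / Vdev else 0
    return(list(g = g, K = K, achieved = corr_of(g, K)))
  }
  if (Vdev <= 1e-12) {
    # no subject deviation to load on: adjust the noise floor if feasible
    if (sign(C) == sign(rho) && (C / rho)^2 > V_T) {
      return(list(g = 0, K = (C / rho)^2 - V_T, achieved = rho))
    }
    warning("within-subject correlation target unattainable without ",
            "subject-level weight variation; best effort used")
    return(list(g = 0, K = K, achieved = corr_of(0, K)))
  }
  for (infl in c(1, 1.5, 2, 4, 8, 16, 32)) {
    Ki <- K * infl
    a <- Vdev * (Vdev - rho^2)
    b <- 2 * C * Vdev
    cc <- C^2 - rho^2 * (V_T + Ki)
    disc <- b^2 - 4 * a * cc
    roots <- if (abs(a) < 1e-14) {
      if (abs(b) > 1e-14) -cc / b else numeric(0)
    } else if (disc >= 0) {
      (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    } else numeric(0)
    ok <- roots[abs(corr_of(roots, Ki) - rho) < 1e-6]
    if (length(ok)) {
      g <- ok[which.min(abs(ok))]
      return(list(g = g, K = Ki, achieved = corr_of(g, Ki)))
    }
  }
  # unreachable target (e.g. sign opposed to the configured median trend):
  # load the subject deviation toward the asymptote sign(g) * sqrt(Vdev)
  g <- sign(rho) * sqrt(10 * (V_T + K) / Vdev)
  warning(sprintf(
    "within-subject correlation target %.3f opposes the configured median trend; best achievable is %.3f",
    rho, corr_of(g, K)))
  list(g = g, K = K, achieved = corr_of(g, K))
}

#' Simulate a longitudinal weight-loss cohort
#'
#' Generates a long-format table (one row per subject and timepoint) with
#' weight and BMI trajectories, serum inflammatory markers and tissue
#' immune-cell density fractions. Weight loss interpolates the configured
#' per-arm median trajectory with a lognormal subject-specific loss
#' multiplier. Each marker is lognormal around its configured per-timepoint
#' median with a subject random intercept and multiplicative noise, plus a
#' component loaded on each subject's weight deviation from the arm-mean
#' trajectory; the loading is calibrated from the realized weights so the
#' within-subject correlation between log marker and weight matches
#' `rho_within` in expectation while per-timepoint medians stay at their
#' configured values.
#'
#' @param params a [cohort_sim_params()].
#' @param seed integer seed overriding `params$seed`.
#' @return data.frame with columns `subject_id, intervention, timepoint,
#'   weight, bmi, crp, il6, tnfa, cd56, cd68, cd3, cd8, foxp3, pd1` and an
#'   `effects` attribute recording, per marker, the target correlation and
#'   calibrated loadings.
#' @examples
#' tab <- simulate_cohort(cohort_sim_params(), seed = 7)
#' nrow(tab)  # 43 subjects x 3 timepoints = 129
#' @export
simulate_cohort <- function(params = cohort_sim_params(),
                            seed = params$seed) {
  stopifnot(inherits(params, "cohort_sim_params"))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  p <- params
  n <- p$n_subjects
  nt <- length(p$timepoints)
  arm <- rep(c("surgery", "diet"), c(p$n_surgery, p$n_diet))
  sid <- sprintf("S%02d", seq_len(n))

  # subject-level effects (truncated at 2 sd to keep weights physical)
  trunc2 <- function(k) pmin(pmax(rnorm(k), -2), 2)
  w_base <- p$baseline_weight_median * exp(p$sigma_weight_base * trunc2(n))
  loss_mult <- exp(p$sigma_loss_re * trunc2(n))
  bmi_base <- p$baseline_bmi_median * exp(p$sigma_bmi_base * trunc2(n))
  height2 <- w_base / bmi_base

  tab <- data.frame(
    subject_id = rep(sid, each = nt),
    intervention = rep(arm, each = nt),
    timepoint = rep(p$timepoints, n),
    stringsAsFactors = FALSE)
  loss <- mapply(function(a, m) p$weight_loss[[a]] * m,
                 rep(arm, each = nt)[seq(1, n * nt, nt)], loss_mult)
  tab$weight <- rep(w_base, each = nt) - as.vector(loss)
  tab$weight <- pmax(tab$weight, 40)  # physical floor
  tab$bmi <- tab$weight / rep(height2, each = nt)

  # standardized within-subject centered weight and its decomposition into
  # the arm-mean trajectory and the subject deviation around it
  sub_mean <- ave(tab$weight, tab$subject_id)
  wc <- tab$weight - sub_mean
  sigma_w <- sqrt(mean(wc^2))
  z <- if (sigma_w > 0) wc / sigma_w else wc
  z_traj <- ave(z, tab$intervention, tab$timepoint)
  dev <- z - z_traj
  Vdev <- mean(dev^2)

  s <- sqrt(log(1 + p$noise_cv^2))
  K0 <- s^2 * (1 - 1 / nt)

  all_meds <- c(p$serum_medians, p$density_medians)
  effects <- data.frame(marker = names(all_meds), rho = NA_real_,
                        g = NA_real_, noise_sd = NA_real_,
                        achieved = NA_real_)
  t_idx <- match(tab$timepoint, p$timepoints)
  for (m in names(all_meds)) {
    M <- all_meds[[m]]
    Tc_t <- log(M) - mean(log(M))
    Tc <- Tc_t[t_idx]
    C <- mean(Tc * z)
    V_T <- mean(Tc^2)
    rho <- if (m %in% names(p$rho_within)) p$rho_within[[m]] else 0
    sol <- .solve_dev_loading(rho, C, V_T, Vdev, K0)
    s_m <- sqrt(sol$K / (1 - 1 / nt))
    sigma_a <- if (m %in% names(p$serum_medians)) p$sigma_subject_serum else
      p$sigma_subject_tissue
    a_i <- rnorm(n, 0, sigma_a)
    eta <- rnorm(n * nt)
    tab[[m]] <- exp(log(M)[t_idx] + rep(a_i, each = nt) + sol$g * dev +
                      s_m * eta)
    effects[effects$marker == m, 2:5] <-
      c(rho, sol$g, s_m, sol$achieved)
  }
  attr(tab, "effects") <- effects
  tab
}
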