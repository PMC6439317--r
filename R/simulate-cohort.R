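#' Simulate a feedlot cohort with intake, gain and metabolic body weight
#'
#' Emulates a feeding-trial cohort of young bulls: average daily gain (ADG,
#' kg/day) and mid-test metabolic body weight (MMBW, kg^0.75, from a body
#' weight of roughly 376 +/- 29 kg) are drawn independently, and daily
#' dry-matter intake (DMI, kg/day) is a linear function of both plus
#' Gaussian noise. The noise is the *planted* residual feed intake: by
#' construction, regressing DMI on ADG and MMBW recovers it.
#'
#' @param n_animals Number of animals (>= 4); the study design uses 98.
#' @param coefficients Named numeric vector `c(intercept, adg, mmbw)` of
#'   regression weights generating DMI. Defaults give intakes around
#'   8-9 kg/day for typical gains and weights.
#' @param noise_sd SD (kg/day) of the RFI noise; 0 yields DMI exactly linear
#'   in (ADG, MMBW).
#' @param seed Integer seed; fixed seed gives identical tables.
#' @return Cohort tibble with columns `animal_id`, `adg`, `mmbw`, `dmi`,
#'   `rfi` (NA until [compute_rfi()]), `group` ("unselected").
#' @export
#' @examples
#' cohort <- simulate_cohort(98, seed = 1)
#' cohort <- compute_rfi(cohort)
#' cohort <- select_extremes(cohort, n_per_group = 9)
#' table(cohort$group)
simulate_cohort <- function(n_animals = 98,
                            coefficients = c(intercept = -1.5, adg = 1.8, mmbw = 0.095),
                            noise_sd = 0.6,
                            seed = NULL) {
  n_animals <- check_count(n_animals, "n_animals", min = 4)
  check_number(noise_sd, "noise_sd", min = 0)
  stopifnot(length(coefficients) == 3L)
  with_seed(seed, {
    bw <- rnorm(n_animals, mean = 376, sd = 29)
    adg <- rnorm(n_animals, mean = 1.1, sd = 0.15)
    mmbw <- bw^0.75
    noise <- if (noise_sd > 0) rnorm(n_animals, 0, noise_sd) else rep(0, n_animals)
    dmi <- coefficients[[1]] + coefficients[[2]] * adg + coefficients[[3]] * mmbw + noise
    tibble(
      animal_id = sprintf("animal_%03d", seq_len(n_animals)),
      adg = adg, mmbw = mmbw, dmi = dmi,
      rfi = NA_real_,
      group = rep("unselected", n_animals)
    )
  })
}

#' Compute residual feed intake (RFI)
#'
#' RFI is the residual of the ordinary least-squares regression of daily
#' dry-matter intake on an intercept, average daily gain and mid-test
#' metabolic body weight. Low RFI marks a high-efficiency animal (it eats
#' less than predicted for its gain and size).
#'
#' @param cohort Cohort tibble with columns `dmi`, `adg`, `mmbw` (>= 3 rows).
#' @return The cohort with the `rfi` column filled and `group` reset to
#'   "unselected". Residuals sum to zero and are orthogonal to the
#'   regressors, as OLS guarantees.
#' @export
compute_rfi <- function(cohort) {
  cohort <- as_tibble(cohort)
  stopifnot(all(c("dmi", "adg", "mmbw") %in% names(cohort)))
  if (nrow(cohort) < 3L) {
    abort("Need at least 3 animals to regress DMI.", class = "feconet_invalid_argument")
  }
  X <- cbind(1, cohort$adg, cohort$mmbw)
  if (qr(X)$rank < 3L) {
    abort("Degenerate design: ADG and MMBW are collinear (or constant).",
          class = "feconet_degenerate_design")
  }
  fit <- lm(dmi ~ adg + mmbw, data = cohort)
  cohort$rfi <- unname(resid(fit))
  cohort$group <- "unselected"
  cohort
}

#' Select divergent feed-efficiency groups from a ranked cohort
#'
#' The `n_per_group` animals with the lowest RFI are labeled HFE (high feed
#' efficiency) and the `n_per_group` with the highest RFI are labeled LFE;
#' everyone else stays "unselected". Ties are broken by `animal_id` order,
#' so repeated runs give identical labels.
#'
#' @param cohort Cohort tibble with `rfi` filled by [compute_rfi()].
#' @param n_per_group Animals per extreme group (the study sequenced 9 + 9).
#' @return The cohort with updated `group` labels.
#' @export
select_extremes <- function(cohort, n_per_group = 9) {
  cohort <- as_tibble(cohort)
  n_per_group <- check_count(n_per_group, "n_per_group", min = 1)
  if (any(is.na(cohort$rfi))) {
    abort("Run compute_rfi() first: `rfi` has missing values.",
          class = "feconet_invalid_argument")
  }
  if (2 * n_per_group > nrow(cohort)) {
    abort("2 * n_per_group exceeds the cohort size.",
          class = "feconet_invalid_argument")
  }
  ord <- order(cohort$rfi, cohort$animal_id)
  cohort$group <- "unselected"
  cohort$group[ord[seq_len(n_per_group)]] <- "HFE"
  cohort$group[ord[seq(nrow(cohort) - n_per_group + 1L, nrow(cohort))]] <- "LFE"
  cohort
}
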